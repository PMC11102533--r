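#' Plot a confusion matrix as a contingency tile chart
#'
#' @param object a [confusion_matrix()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- tidy(object)
  df$truth <- factor(df$truth, levels = rev(rownames(object)))
  df$predicted <- factor(df$predicted, levels = colnames(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile(colour = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 guide = "none") +
    ggplot2::labs(x = "classifier", y = "ground truth") +
    ggplot2::theme_minimal()
}

#' Plot a pattern-deviation matrix
#'
#' Field-space view of a [pd_matrix()]: one point per locus, sized and
#' shaded by significance category.
#'
#' @param object a [pd_matrix()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pd_matrix <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   size = .data$category,
                                   colour = .data$category)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::scale_size_manual(
      values = stats::setNames(c(0.8, 1.6, 2.4, 3.2, 4), pd_categories())) +
    ggplot2::scale_colour_manual(
      values = stats::setNames(grDevices::gray(c(0.75, 0.6, 0.45, 0.25, 0)),
                               pd_categories())) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "eccentricity (deg, temporal +)",
                  y = "eccentricity (deg, superior +)",
                  title = paste("pattern deviation,", pd_pattern(object))) +
    ggplot2::theme_minimal()
}

#' Overlay the superimposed grid on a parsed plot image
#'
#' Reproduces the interpretability view of the parser: the plot image with
#' the detected panel bounds and the sampling grid drawn on top, coloured by
#' the classified category.
#'
#' @param image grayscale matrix (or file path).
#' @param pd a parsed [pd_matrix()] carrying a `diagnostics` attribute
#'   (from [parse_pattern_plot()]).
#' @return a ggplot.
#' @export
plot_overlay <- function(image, pd) {
  if (is.character(image)) image <- read_plot_image(image)
  diag <- attr(pd, "diagnostics")
  if (is.null(diag)) stop("pd has no diagnostics; parse it first", call. = FALSE)
  g <- diag$geometry
  img_df <- expand.grid(row = seq_len(nrow(image)), col = seq_len(ncol(image)))
  img_df$value <- as.vector(image)
  s <- diag$samples
  w <- 0.8 * 6 * (g$ppd_x + g$ppd_y) / 2
  ggplot2::ggplot() +
    ggplot2::geom_raster(data = img_df,
                         ggplot2::aes(x = .data$col, y = -.data$row,
                                      fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::annotate("rect", xmin = g$left, xmax = g$right,
                      ymin = -g$bottom, ymax = -g$top,
                      colour = "red", fill = NA) +
    ggplot2::geom_rect(data = s,
                       ggplot2::aes(xmin = .data$col - w / 2,
                                    xmax = .data$col + w / 2,
                                    ymin = -.data$row - w / 2,
                                    ymax = -.data$row + w / 2,
                                    colour = .data$category),
                       fill = NA, linewidth = 0.3) +
    ggplot2::coord_fixed() +
    ggplot2::labs(colour = "category") +
    ggplot2::theme_void()
}
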