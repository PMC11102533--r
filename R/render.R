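#' Rendering style for synthetic pattern-deviation plots
#'
#' Controls how [render_pattern_plot()] draws a Humphrey-style
#' pattern-deviation panel: grid pitch in pixels, whether a rectangular frame
#' is drawn around the panel, random jitter of symbol centres, background
#' level, and which glyph family is used. Defaults render a clean framed
#' plot, which is what clinical printouts look like; the robustness suites
#' turn jitter and noise on explicitly.
#'
#' @param cell_px pixels per 6-degree grid cell (>= 16).
#' @param frame draw a 2 px rectangular frame around the panel?
#' @param jitter_px maximum symbol-centre jitter in pixels (<= `cell_px / 8`).
#' @param background background grayscale level in (0, 1].
#' @param glyph_family one of [glyph_families()].
#' @param margin_px white margin between the frame and the outermost cells.
#' @param noise proportion of background pixels flipped to ink (salt noise).
#' @return an object of class `render_style`.
#' @export
render_style <- function(cell_px = 32, frame = TRUE, jitter_px = 0,
                         background = 1, glyph_family = "stipple",
                         margin_px = NULL, noise = 0) {
  cell_px <- as.integer(cell_px)
  if (is.na(cell_px) || cell_px < 16L) {
    stop("cell_px must be at least 16", call. = FALSE)
  }
  if (jitter_px > cell_px / 8) {
    stop("jitter_px must not exceed cell_px / 8", call. = FALSE)
  }
  if (background <= 0 || background > 1) {
    stop("background must be in (0, 1]", call. = FALSE)
  }
  structure(
    list(cell_px = cell_px, frame = isTRUE(frame),
         jitter_px = as.numeric(jitter_px), background = background,
         glyph_family = match.arg(glyph_family, glyph_families()),
         margin_px = if (is.null(margin_px)) ceiling(cell_px / 2)
                     else as.integer(margin_px),
         noise = noise),
    class = "render_style"
  )
}

#' Plot geometry
#'
#' Pixel-space location of a pattern-deviation panel: its bounding box, the
#' pixel position of the visual-field origin, and the pixel-per-degree scale.
#' Pixel rows increase downwards while field y increases superiorly; all
#' degree-to-pixel conversions go through this object.
#'
#' @param left,top,right,bottom panel bounding box in pixels (inclusive).
#' @param origin_row,origin_col pixel position of the field origin (0, 0).
#' @param ppd_x,ppd_y pixels per degree along each axis (> 0).
#' @param img_dim image dimensions `c(rows, cols)`.
#' @return an object of class `plot_geometry`.
#' @export
plot_geometry <- function(left, top, right, bottom, origin_row, origin_col,
                          ppd_x, ppd_y, img_dim) {
  if (right <= left || bottom <= top) {
    stop("degenerate plot bounding box", call. = FALSE)
  }
  if (ppd_x <= 0 || ppd_y <= 0) stop("pixel scale must be positive", call. = FALSE)
  structure(
    list(left = left, top = top, right = right, bottom = bottom,
         origin_row = origin_row, origin_col = origin_col,
         ppd_x = ppd_x, ppd_y = ppd_y, img_dim = as.integer(img_dim)),
    class = "plot_geometry"
  )
}

#' @export
print.plot_geometry <- function(x, ...) {
  cat("<plot_geometry> bbox [", x$left, ",", x$top, "]-[", x$right, ",",
      x$bottom, "] px, origin (", round(x$origin_col, 1), ",",
      round(x$origin_row, 1), "), ", round(x$ppd_x, 2), " px/deg\n", sep = "")
  invisible(x)
}

# degree extent of the printed panel (3 deg beyond the outermost loci)
chart_extent <- function(pattern, eye) {
  loci <- test_pattern_loci(pattern)
  cx <- chart_x(loci$x, eye)
  list(xmin = min(cx) - 3, xmax = max(cx) + 3,
       ymin = min(loci$y) - 3, ymax = max(loci$y) + 3)
}

#' Render a synthetic pattern-deviation plot
#'
#' Draws a Humphrey-style pattern-deviation panel for a given
#' [pd_matrix()]: a bordered panel with one probability symbol per test
#' locus on the canonical grid, mirrored for left eyes. Rendering is
#' deterministic given `(pd, eye, style, seed)`, and the true geometry and
#' per-locus categories are returned alongside the image so parsed output
#' can be checked against ground truth.
#'
#' @param pd a [pd_matrix()].
#' @param eye `"right"` or `"left"`.
#' @param style a [render_style()].
#' @param seed integer seed driving jitter and noise (unused when both are
#'   off, but still recorded).
#' @return an object of class `rendered_plot`: a list with elements `image`
#'   (grayscale matrix), `geometry` ([plot_geometry()]), `loci` (tibble with
#'   the true pixel centre and category of every locus), `pattern`, `eye`,
#'   `style`, `seed`.
#' @examples
#' rp <- render_pattern_plot(pd_matrix("24-2"), "right")
#' dim(rp$image)
#' @export
render_pattern_plot <- function(pd, eye = "right", style = render_style(),
                                seed = 0L) {
  validate_pd_matrix(pd)
  eye <- match_eye(eye)
  stopifnot(inherits(style, "render_style"))
  pattern <- pd_pattern(pd)
  ext <- chart_extent(pattern, eye)
  ppd <- style$cell_px / 6
  margin <- style$margin_px
  panel_w <- round((ext$xmax - ext$xmin) * ppd)
  panel_h <- round((ext$ymax - ext$ymin) * ppd)
  W <- panel_w + 2L * margin
  H <- panel_h + 2L * margin
  img <- matrix(style$background, H, W)

  left <- margin + 1L; top <- margin + 1L
  right <- margin + panel_w; bottom <- margin + panel_h
  if (style$frame) {
    img[c(top, top + 1L, bottom - 1L, bottom), left:right] <- 0
    img[top:bottom, c(left, left + 1L, right - 1L, right)] <- 0
  }

  origin_col <- left + (0 - ext$xmin) * ppd
  origin_row <- top + ext$ymax * ppd

  loci <- dplyr::mutate(
    tibble::as_tibble(pd),
    col = origin_col + chart_x(.data$x, eye) * ppd,
    row = origin_row - .data$y * ppd
  )

  withr::with_seed(as.integer(seed), {
    if (style$jitter_px > 0) {
      j <- round(style$jitter_px)
      loci$col <- loci$col + sample(-j:j, nrow(loci), replace = TRUE)
      loci$row <- loci$row + sample(-j:j, nrow(loci), replace = TRUE)
    }
    for (i in seq_len(nrow(loci))) {
      mask <- glyph_mask(loci$category[i], style$cell_px, style$glyph_family)
      img <- stamp_mask(img, mask, loci$row[i], loci$col[i])
    }
    if (style$noise > 0) {
      flip <- which(stats::runif(length(img)) < style$noise)
      img[flip] <- 0
    }
  })

  structure(
    list(image = img,
         geometry = plot_geometry(left, top, right, bottom, origin_row,
                                  origin_col, ppd, ppd, dim(img)),
         loci = loci, pattern = pattern, eye = eye, style = style,
         seed = as.integer(seed)),
    class = "rendered_plot"
  )
}

# draw a glyph mask centred at (row, col); ink = 0
stamp_mask <- function(img, mask, row, col) {
  h <- nrow(mask); w <- ncol(mask)
  r0 <- round(row - (h + 1) / 2)
  c0 <- round(col - (w + 1) / 2)
  ij <- which(mask, arr.ind = TRUE)
  rr <- r0 + ij[, 1]; cc <- c0 + ij[, 2]
  keep <- rr >= 1 & rr <= nrow(img) & cc >= 1 & cc <= ncol(img)
  img[cbind(rr[keep], cc[keep])] <- 0
  img
}

#' @export
print.rendered_plot <- function(x, ...) {
  cat("<rendered_plot> ", x$pattern, " ", x$eye, " eye, ",
      nrow(x$loci), " loci, ", paste(dim(x$image), collapse = "x"),
      " px (", x$style$glyph_family, " glyphs)\n", sep = "")
  invisible(x)
}
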