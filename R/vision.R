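#' Locate the pattern-deviation panel in an image
#'
#' Binarises the image (global Otsu) and finds the panel's rectangular frame
#' as the outermost long horizontal and vertical ink runs. When no frame is
#' present, falls back to the tight bounding box of symbol mass dilated by
#' half a cell, followed by grid refinement (per-locus ink centroids
#' regressed on the canonical grid), which recovers the exact scale that the
#' bounding box alone cannot (glyph extent varies by category).
#'
#' The degree extent of the panel — hence the origin and pixel-per-degree
#' scale — depends on the test pattern and the eye (the 24-2 layout is
#' nasally asymmetric), so both are required.
#'
#' @param image grayscale matrix, RGB array, or file path.
#' @param pattern `"24-2"` or `"30-2"`.
#' @param eye `"right"` or `"left"`.
#' @param refine run grid refinement after the initial estimate?
#' @return a [plot_geometry()].
#' @export
detect_plot_bounds <- function(image, pattern, eye, refine = TRUE) {
  if (is.character(image)) image <- read_plot_image(image)
  ink <- binarize_image(as_gray(image))
  fl <- frame_lines(ink)
  geom <- detect_bounds_ink(ink, pattern, eye, fl)
  if (refine) geom <- refine_geometry(erase_frame(ink, fl), geom, pattern, eye)
  geom
}

frame_lines <- function(ink) {
  list(rows = long_run_lines(ink), cols = long_run_lines(t(ink)))
}

# frame lines sit well clear of every glyph, so whole rows/columns can be
# blanked without touching symbol ink; this keeps frame pixels out of the
# sampling windows of edge-row loci (a real hazard at small cell sizes)
erase_frame <- function(ink, fl) {
  if (length(fl$rows)) ink[fl$rows, ] <- FALSE
  if (length(fl$cols)) ink[, fl$cols] <- FALSE
  ink
}

detect_bounds_ink <- function(ink, pattern, eye, fl = frame_lines(ink)) {
  pattern <- match_pattern(pattern)
  eye <- match_eye(eye)
  if (!any(ink)) stop("no plot found: image contains no symbol mass", call. = FALSE)
  ext <- chart_extent(pattern, eye)

  rcl <- line_clusters(fl$rows)
  ccl <- line_clusters(fl$cols)
  if (length(rcl) > 2L || length(ccl) > 2L) {
    stop("ambiguous plot bounds: multiple candidate panels (frame lines at rows ",
         paste(vapply(rcl, function(cl) paste0(min(cl), "-", max(cl)), ""),
               collapse = ", "),
         "; cols ",
         paste(vapply(ccl, function(cl) paste0(min(cl), "-", max(cl)), ""),
               collapse = ", "), ")", call. = FALSE)
  }

  if (length(rcl) == 2L && length(ccl) == 2L) {
    top <- min(rcl[[1]]); bottom <- max(rcl[[2]])
    left <- min(ccl[[1]]); right <- max(ccl[[2]])
  } else {
    # frameless: tight bbox of ink, dilated by half a cell; the cell size is
    # itself estimated from the bbox assuming ~0.7-cell glyphs at the edges
    dark <- which(ink, arr.ind = TRUE)
    r <- range(dark[, 1]); c <- range(dark[, 2])
    # bbox spans the locus extent plus ~0.35 cell (2.1 deg) of glyph on each
    # side; the panel edge sits a further 0.9 deg out (3 deg beyond the loci)
    ppd0 <- mean(c((diff(c) + 1) / (ext$xmax - ext$xmin - 6 + 4.2),
                   (diff(r) + 1) / (ext$ymax - ext$ymin - 6 + 4.2)))
    top <- r[1] - 0.9 * ppd0
    bottom <- r[2] + 0.9 * ppd0
    left <- c[1] - 0.9 * ppd0
    right <- c[2] + 0.9 * ppd0
  }

  ppd_x <- (right - left) / (ext$xmax - ext$xmin)
  ppd_y <- (bottom - top) / (ext$ymax - ext$ymin)
  if (ppd_x <= 0 || ppd_y <= 0) {
    stop("no plot found: degenerate symbol extent", call. = FALSE)
  }
  plot_geometry(left, top, right, bottom,
                origin_row = top + ext$ymax * ppd_y,
                origin_col = left + (0 - ext$xmin) * ppd_x,
                ppd_x = ppd_x, ppd_y = ppd_y, img_dim = dim(ink))
}

# indices of lines (rows of m) whose longest contiguous ink run spans at
# least half the image: frame lines, not symbol rows
long_run_lines <- function(m) {
  runlen <- apply(m, 1, function(v) {
    r <- rle(v)
    runs <- r$lengths[r$values]
    if (length(runs)) max(runs) else 0L
  })
  which(runlen >= 0.5 * ncol(m))
}

line_clusters <- function(idx, gap = 4L) {
  if (length(idx) == 0L) return(list())
  breaks <- c(0L, which(diff(idx) > gap), length(idx))
  lapply(seq_len(length(breaks) - 1L),
         function(i) idx[(breaks[i] + 1L):breaks[i + 1L]])
}

#' Refine plot geometry against the canonical grid
#'
#' Given an initial geometry, measures the ink centroid in a window around
#' every predicted locus centre and regresses the centroids on the canonical
#' grid coordinates, re-estimating origin and scale. Every locus carries ink
#' (the not-significant symbol is a visible dot), so all loci inform the fit.
#' Iterated a few times so that loci initially clipped by a poor scale
#' estimate are re-measured with better windows.
#'
#' @param ink logical ink mask.
#' @param geom initial [plot_geometry()].
#' @inheritParams detect_plot_bounds
#' @param iterations number of refinement passes.
#' @return a refined [plot_geometry()].
#' @keywords internal
refine_geometry <- function(ink, geom, pattern, eye, iterations = 3L) {
  loci <- test_pattern_loci(match_pattern(pattern))
  cx <- chart_x(loci$x, eye)
  for (it in seq_len(iterations)) {
    w <- max(5L, round(0.8 * 6 * (geom$ppd_x + geom$ppd_y) / 2))
    pred_col <- geom$origin_col + cx * geom$ppd_x
    pred_row <- geom$origin_row - loci$y * geom$ppd_y
    cent <- centroid_grid(ink, pred_row, pred_col, w)
    ok <- is.finite(cent$row) & is.finite(cent$col)
    if (sum(ok) < nrow(loci) * 0.5) break
    fx <- stats::lm.fit(cbind(1, cx[ok]), cent$col[ok])$coefficients
    fy <- stats::lm.fit(cbind(1, -loci$y[ok]), cent$row[ok])$coefficients
    if (fx[2] <= 0 || fy[2] <= 0) break
    ext <- chart_extent(pattern, eye)
    geom <- plot_geometry(
      left = fx[1] + ext$xmin * fx[2], top = fy[1] - ext$ymax * fy[2],
      right = fx[1] + ext$xmax * fx[2], bottom = fy[1] - ext$ymin * fy[2],
      origin_row = fy[1], origin_col = fx[1],
      ppd_x = fx[2], ppd_y = fy[2], img_dim = geom$img_dim
    )
  }
  geom
}

centroid_grid <- function(ink, rows, cols, w) {
  n <- length(rows)
  out_r <- out_c <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    rr <- seq.int(round(rows[i] - w / 2), length.out = w)
    cc <- seq.int(round(cols[i] - w / 2), length.out = w)
    rr <- rr[rr >= 1 & rr <= nrow(ink)]
    cc <- cc[cc >= 1 & cc <= ncol(ink)]
    if (!length(rr) || !length(cc)) next
    win <- ink[rr, cc, drop = FALSE]
    d <- which(win, arr.ind = TRUE)
    if (nrow(d) == 0L) next
    out_r[i] <- mean(rr[d[, 1]])
    out_c[i] <- mean(cc[d[, 2]])
  }
  list(row = out_r, col = out_c)
}

#' Superimpose the canonical locus grid on a plot geometry
#'
#' Returns the pixel centre of every test locus of a pattern under a
#' geometry. Left-eye layouts are the x-mirror of right-eye layouts.
#'
#' @inheritParams detect_plot_bounds
#' @param geom a [plot_geometry()].
#' @return a tibble with columns `x`, `y` (degrees), `row`, `col` (pixels).
#' @export
map_loci <- function(geom, pattern, eye) {
  stopifnot(inherits(geom, "plot_geometry"))
  loci <- test_pattern_loci(match_pattern(pattern))
  out <- dplyr::mutate(
    loci,
    row = geom$origin_row - .data$y * geom$ppd_y,
    col = geom$origin_col + chart_x(.data$x, eye) * geom$ppd_x
  )
  if (any(out$row < 1 | out$row > geom$img_dim[1] |
          out$col < 1 | out$col > geom$img_dim[2])) {
    stop("geometry error: locus centre falls outside the image", call. = FALSE)
  }
  out
}

#' Classify the probability symbol in one sampling window
#'
#' Measures the dark-pixel fraction in a square window of 0.8x the grid
#' pitch around a locus centre and assigns the category of the nearest
#' calibration reference (log-scale distance, symbol bounding-box size as
#' secondary feature). The default calibration is rendered once at a
#' canonical pitch; ink fractions are close to scale-invariant, so it
#' transfers across plot sizes. Near-boundary samples resolve toward the less
#' significant category and are flagged low-confidence, conservative against
#' false severity inflation.
#'
#' @param ink logical ink mask.
#' @param row,col pixel centre of the sampling window.
#' @param pitch_px grid pitch in pixels.
#' @param calibration a [symbol_calibration()] table.
#' @param window_frac window side as fraction of pitch.
#' @param margin relative distance ratio under which a competing category is
#'   considered a near-tie.
#' @return a list with `category` (ordered factor), `ink_fraction`,
#'   `low_confidence`.
#' @export
classify_symbol <- function(ink, row, col, pitch_px,
                            calibration = symbol_calibration(),
                            window_frac = 0.8, margin = 0.12) {
  w <- max(3L, round(window_frac * pitch_px))
  st <- window_stats(ink, row, col, w)
  eps <- 0.003
  d_ink <- abs(log(st$ink_fraction + eps) - log(calibration$ink_fraction + eps))
  d_bbox <- abs(log(st$bbox_fraction + eps) - log(calibration$bbox_fraction + eps))
  score <- d_ink + 0.3 * d_bbox
  cat_of <- as.character(calibration$category)
  best <- order(score, match(cat_of, pd_categories()))[1]  # ties: less significant
  others <- cat_of != cat_of[best]
  low_conf <- any(others) &&
    (min(score[others]) - score[best]) < log(1 + margin)
  list(category = pd_category(cat_of[best]),
       ink_fraction = st$ink_fraction,
       low_confidence = low_conf)
}

#' Parse a pattern-deviation plot image into a matrix
#'
#' The full image-to-matrix mechanism: binarise, locate the panel
#' ([detect_plot_bounds()]), superimpose the canonical locus grid
#' ([map_loci()]), and classify the symbol at every locus
#' ([classify_symbol()]). The result is the same [pd_matrix()] structure the
#' rule engine consumes; per-locus diagnostics (geometry, ink fractions,
#' low-confidence flags) are attached as an attribute.
#'
#' @inheritParams detect_plot_bounds
#' @param calibration optional [symbol_calibration()] table; by default
#'   derived at the detected pitch.
#' @param window_frac sampling-window side as fraction of the grid pitch.
#' @return a [pd_matrix()] with attribute `diagnostics` (list: `geometry`,
#'   `samples` tibble, `warnings` character vector).
#' @examples
#' rp <- render_pattern_plot(pd_matrix("24-2"), "right")
#' pd <- parse_pattern_plot(rp$image, "24-2", "right")
#' count_depressed(pd, "p5")
#' @export
parse_pattern_plot <- function(image, pattern, eye, refine = TRUE,
                               calibration = NULL, window_frac = 0.8) {
  if (is.character(image)) image <- read_plot_image(image)
  pattern <- match_pattern(pattern)
  eye <- match_eye(eye)
  ink <- binarize_image(as_gray(image))
  fl <- frame_lines(ink)
  geom <- detect_bounds_ink(ink, pattern, eye, fl)
  ink <- erase_frame(ink, fl)
  if (refine) geom <- refine_geometry(ink, geom, pattern, eye)
  centers <- map_loci(geom, pattern, eye)
  pitch <- 6 * (geom$ppd_x + geom$ppd_y) / 2
  if (is.null(calibration)) calibration <- symbol_calibration()

  cls <- purrr::pmap(centers[, c("row", "col")], function(row, col) {
    classify_symbol(ink, row, col, pitch, calibration, window_frac)
  })
  samples <- dplyr::mutate(
    centers,
    ink_fraction = purrr::map_dbl(cls, "ink_fraction"),
    category = pd_category(purrr::map_chr(cls, ~ as.character(.x$category))),
    low_confidence = purrr::map_lgl(cls, "low_confidence")
  )
  warnings <- character()
  if (any(samples$low_confidence)) {
    lc <- samples[samples$low_confidence, ]
    warnings <- sprintf(
      "low-confidence symbol at (%g, %g): ink fraction %.3f near a calibration boundary",
      lc$x, lc$y, lc$ink_fraction)
  }
  pd <- new_pd_matrix(samples[, c("x", "y", "category")], pattern)
  attr(pd, "diagnostics") <- list(geometry = geom, samples = samples,
                                  warnings = warnings)
  pd
}
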