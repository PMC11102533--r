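# Probability-symbol glyphs.
#
# The five categories of a pattern-deviation plot are drawn with glyphs whose
# ink density increases monotonically with significance — the property the
# parser's 1-D ink-fraction feature relies on. Two glyph families are
# provided so the parser's tolerance of different printout styles can be
# exercised; their densities interleave consistently (every "stipple" and
# "geometric" glyph of a category is closer to its own category than to any
# glyph of another), so one calibration table covers both.

#' @rdname glyph_mask
#' @export
glyph_families <- function() c("stipple", "geometric")

#' Render one probability-symbol glyph
#'
#' Returns a logical ink mask of size `cell_px` x `cell_px` for a
#' significance category. Glyphs stay within the central 80% of the cell so
#' neighbouring sampling windows never overlap.
#'
#' @param category one of [pd_categories()].
#' @param cell_px cell size in pixels (>= 16; below that the five glyphs are
#'   not reliably distinguishable).
#' @param family glyph family, one of [glyph_families()].
#' @return logical matrix, TRUE = ink.
#' @export
glyph_mask <- function(category, cell_px, family = "stipple") {
  family <- match.arg(family, glyph_families())
  category <- as.character(pd_category(category))
  cell_px <- as.integer(cell_px)
  if (is.na(cell_px) || cell_px < 16L) {
    stop("cell_px must be at least 16 to distinguish the five glyphs",
         call. = FALSE)
  }
  m <- matrix(FALSE, cell_px, cell_px)
  ctr <- (cell_px + 1) / 2
  # All glyphs use compact features no finer than ~cell/8 pixels so their
  # ink fraction survives resampling and re-binarisation; the two families
  # straddle each category's density band from below and above.
  if (family == "stipple") {
    m <- switch(category,
      NS = stamp_rect(m, ctr, ctr, max(2L, round(cell_px / 10)),
                      max(2L, round(cell_px / 10))),
      P5 = stamp_rect(m, ctr, ctr, round(cell_px / 5), round(cell_px / 5)),
      P2 = {
        s2 <- round(cell_px / 6)
        d <- round(0.25 * cell_px)
        for (k in -1:1) m <- stamp_rect(m, ctr + k * d, ctr + k * d, s2, s2)
        m
      },
      P1 = {
        s3 <- round(cell_px / 6)
        r <- 0.27 * cell_px
        m <- stamp_rect(m, ctr, ctr, s3, s3)
        for (a in seq(0, 300, by = 60) * pi / 180) {
          m <- stamp_rect(m, ctr + r * sin(a), ctr + r * cos(a), s3, s3)
        }
        m
      },
      P05 = stamp_rect(m, ctr, ctr, round(0.72 * cell_px), round(0.72 * cell_px))
    )
  } else {
    m <- switch(category,
      NS = stamp_rect(m, ctr, ctr, max(2L, round(cell_px / 10)),
                      max(2L, round(cell_px / 10))),
      P5 = stamp_diamond(m, ctr, ctr, max(2L, round(0.135 * cell_px))),
      P2 = stamp_disc(m, ctr, ctr, max(3L, round(0.17 * cell_px))),
      P1 = stamp_diamond(m, ctr, ctr, round(0.3 * cell_px)),
      P05 = stamp_disc(m, ctr, ctr, round(0.37 * cell_px))
    )
  }
  m
}

stamp_rect <- function(m, cy, cx, h, w) {
  rows <- seq.int(round(cy - h / 2), length.out = max(1L, round(h)))
  cols <- seq.int(round(cx - w / 2), length.out = max(1L, round(w)))
  rows <- rows[rows >= 1 & rows <= nrow(m)]
  cols <- cols[cols >= 1 & cols <= ncol(m)]
  m[rows, cols] <- TRUE
  m
}

stamp_disc <- function(m, cy, cx, r) {
  ij <- which(!is.na(m), arr.ind = TRUE)  # all cells
  d2 <- (ij[, 1] - cy)^2 + (ij[, 2] - cx)^2
  m[ij[d2 <= r^2, , drop = FALSE]] <- TRUE
  m
}

stamp_diamond <- function(m, cy, cx, r) {
  ij <- which(!is.na(m), arr.ind = TRUE)
  d <- abs(ij[, 1] - cy) + abs(ij[, 2] - cx)
  m[ij[d <= r, , drop = FALSE]] <- TRUE
  m
}

#' Symbol calibration table
#'
#' Reference ink fractions for the five probability symbols, measured on the
#' package's own glyphs rendered at a given grid pitch. The parser classifies
#' a sampled cell to the category of the nearest reference fraction (in log
#' scale, with the symbol bounding-box size as tie-breaker), so the table
#' doubles as the classifier's decision surface. Re-derive it at a different
#' pitch (or from a legend strip rendered with known categories) to
#' recalibrate.
#'
#' Ink fractions are nearly scale-invariant, so one table rendered at a
#' canonical pitch (48 px, large enough that integer rounding of glyph
#' dimensions is negligible) serves all plot sizes; the pitch argument
#' exists for explicit recalibration, e.g. from a legend strip.
#'
#' @param pitch_px grid pitch (pixels between adjacent loci).
#' @param families glyph families to include.
#' @param window_frac sampling-window side as a fraction of the pitch.
#' @return a tibble with columns `family`, `category`, `ink_fraction`,
#'   `bbox_fraction`.
#' @export
symbol_calibration <- function(pitch_px = 48, families = glyph_families(),
                               window_frac = 0.8) {
  cell <- max(16L, round(pitch_px))
  purrr::map_dfr(families, function(fam) {
    purrr::map_dfr(pd_categories(), function(cat) {
      mask <- glyph_mask(cat, cell, fam)
      f <- window_stats(mask, (cell + 1) / 2, (cell + 1) / 2,
                        round(window_frac * cell))
      tibble::tibble(family = fam, category = cat,
                     ink_fraction = f$ink_fraction,
                     bbox_fraction = f$bbox_fraction)
    })
  })
}

# ink fraction and bounding-box area fraction within a w x w window
window_stats <- function(ink, cy, cx, w) {
  rows <- seq.int(round(cy - w / 2), length.out = w)
  cols <- seq.int(round(cx - w / 2), length.out = w)
  rows <- rows[rows >= 1 & rows <= nrow(ink)]
  cols <- cols[cols >= 1 & cols <= ncol(ink)]
  if (length(rows) == 0L || length(cols) == 0L) {
    stop("sampling window lies outside the image", call. = FALSE)
  }
  win <- ink[rows, cols, drop = FALSE]
  n <- length(win)
  dark <- which(win, arr.ind = TRUE)
  if (nrow(dark) == 0L) {
    return(list(ink_fraction = 0, bbox_fraction = 0))
  }
  bbox <- (diff(range(dark[, 1])) + 1) * (diff(range(dark[, 2])) + 1)
  list(ink_fraction = nrow(dark) / n, bbox_fraction = bbox / n)
}
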