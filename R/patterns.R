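#' Canonical Humphrey test-pattern locus layouts
#'
#' Test loci of the 24-2 and 30-2 patterns in visual-field coordinates
#' (degrees; x positive temporal, y positive superior; the field coordinates
#' of a locus are the same for both eyes — only the printed chart mirrors).
#' Loci sit on a 6-degree grid offset 3 degrees from both meridians. The 24-2
#' pattern has 54 loci, including one extra nasal locus at 27 degrees on each
#' of the two central rows; the 30-2 pattern has 76.
#'
#' @param pattern `"24-2"` or `"30-2"`.
#' @return a tibble with columns `x`, `y` (degrees), ordered top row first,
#'   nasal to temporal within a row.
#' @examples
#' nrow(test_pattern_loci("24-2"))  # 54
#' nrow(test_pattern_loci("30-2"))  # 76
#' @export
test_pattern_loci <- function(pattern = c("24-2", "30-2")) {
  pattern <- match.arg(pattern)
  half <- function(rows) {
    purrr::map_dfr(rows, function(r) tibble::tibble(x = r$x, y = r$y))
  }
  if (pattern == "24-2") {
    rows <- list(
      list(y = 21, x = seq(-9, 9, by = 6)),
      list(y = 15, x = seq(-15, 15, by = 6)),
      list(y = 9,  x = seq(-21, 21, by = 6)),
      list(y = 3,  x = c(-27, seq(-21, 21, by = 6)))
    )
  } else {
    rows <- list(
      list(y = 27, x = seq(-9, 9, by = 6)),
      list(y = 21, x = seq(-15, 15, by = 6)),
      list(y = 15, x = seq(-21, 21, by = 6)),
      list(y = 9,  x = seq(-27, 27, by = 6)),
      list(y = 3,  x = seq(-27, 27, by = 6))
    )
  }
  upper <- half(rows)
  lower <- dplyr::mutate(upper, y = -.data$y)
  out <- dplyr::bind_rows(upper, lower)
  dplyr::arrange(out, dplyr::desc(.data$y), .data$x)
}

#' @rdname test_pattern_loci
#' @export
pattern_locus_count <- function(pattern = c("24-2", "30-2")) {
  pattern <- match.arg(pattern)
  if (pattern == "24-2") 54L else 76L
}

#' Chart (printed-page) x coordinate of a locus
#'
#' On a printed chart the horizontal axis runs nasal-to-temporal for the right
#' eye and is mirrored for the left eye; field coordinates (x positive
#' temporal) therefore map to page coordinates through the eye.
#'
#' @param x field x in degrees (positive temporal).
#' @param eye `"right"` or `"left"`.
#' @return page x in degrees (positive to the right of the page).
#' @keywords internal
chart_x <- function(x, eye) {
  eye <- match_eye(eye)
  if (eye == "right") x else -x
}

match_eye <- function(eye) {
  eye <- tolower(as.character(eye))
  if (eye %in% c("right", "od", "r")) return("right")
  if (eye %in% c("left", "os", "l")) return("left")
  stop("eye must be \"right\" or \"left\", got ", eye, call. = FALSE)
}

match_pattern <- function(pattern) {
  pattern <- as.character(pattern)
  pattern <- sub("^P?", "", gsub("_", "-", toupper(pattern)))
  if (!pattern %in% c("24-2", "30-2")) {
    stop("pattern must be \"24-2\" or \"30-2\", got ", pattern, call. = FALSE)
  }
  pattern
}
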