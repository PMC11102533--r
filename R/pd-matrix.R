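#' Pattern-deviation matrix
#'
#' A pattern-deviation matrix records, for every test locus of a pattern, the
#' significance category of its probability symbol. It is stored as a tibble
#' with columns `x`, `y` (field degrees) and `category` (ordered factor, see
#' [pd_categories()]), in canonical order (top row first, nasal to temporal),
#' with the pattern name attached as an attribute.
#'
#' @param pattern `"24-2"` or `"30-2"`.
#' @param category a single category recycled to all loci, or a vector with
#'   one entry per locus in canonical order.
#' @param cells alternatively, a data frame with columns `x`, `y`, `category`
#'   covering the pattern's loci exactly.
#' @return a `pd_matrix` tibble.
#' @examples
#' pd_matrix("24-2")                      # all loci not significant
#' pd_matrix("24-2", c(rep("P1", 3), rep("NS", 51)))
#' @export
pd_matrix <- function(pattern = c("24-2", "30-2"), category = "NS", cells = NULL) {
  pattern <- match_pattern(pattern)
  loci <- test_pattern_loci(pattern)
  if (!is.null(cells)) {
    stopifnot(is.data.frame(cells), all(c("x", "y", "category") %in% names(cells)))
    cells <- dplyr::mutate(cells, category = pd_category(.data$category))
    out <- dplyr::left_join(loci, cells, by = c("x", "y"))
    if (anyNA(out$category) || nrow(cells) != nrow(loci)) {
      stop("cells must cover the ", pattern, " loci exactly (",
           nrow(loci), " entries)", call. = FALSE)
    }
  } else {
    if (length(category) == 1L) category <- rep(category, nrow(loci))
    if (length(category) != nrow(loci)) {
      stop("category must have length 1 or ", nrow(loci), call. = FALSE)
    }
    out <- dplyr::mutate(loci, category = pd_category(category))
  }
  new_pd_matrix(out, pattern)
}

new_pd_matrix <- function(tbl, pattern) {
  tbl <- dplyr::arrange(tbl, dplyr::desc(.data$y), .data$x)
  tbl <- tibble::as_tibble(tbl[, c("x", "y", "category")])
  attr(tbl, "pattern") <- pattern
  class(tbl) <- c("pd_matrix", class(tbl))
  tbl
}

#' @export
print.pd_matrix <- function(x, ...) {
  cat("<pd_matrix> pattern ", pd_pattern(x), ", ",
      sum(x$category > "NS"), "/", nrow(x), " loci depressed at P<5%\n", sep = "")
  NextMethod()
}

#' @rdname pd_matrix
#' @param pd a `pd_matrix`.
#' @export
pd_pattern <- function(pd) {
  p <- attr(pd, "pattern", exact = TRUE)
  if (is.null(p)) stop("not a pd_matrix: missing pattern attribute", call. = FALSE)
  p
}

validate_pd_matrix <- function(pd) {
  pattern <- pd_pattern(pd)
  loci <- test_pattern_loci(pattern)
  if (nrow(pd) != nrow(loci) ||
      !identical(paste(pd$x, pd$y), paste(loci$x, loci$y))) {
    stop("pd_matrix loci do not match the canonical ", pattern, " layout",
         call. = FALSE)
  }
  if (anyNA(pd$category)) stop("pd_matrix has missing categories", call. = FALSE)
  invisible(pd)
}

#' Count depressed pattern-deviation loci
#'
#' The HPA pattern-deviation criteria use the proportion of loci depressed
#' below P < 5% (any of the four depressed symbols) and below P < 1% (the two
#' most significant symbols).
#'
#' @param pd a [pd_matrix()].
#' @param level `"p5"` (categories P5, P2, P1, P05) or `"p1"` (P1, P05).
#' @return a list with integer elements `count` and `total`.
#' @examples
#' count_depressed(pd_matrix("24-2"), "p5")
#' @export
count_depressed <- function(pd, level = c("p5", "p1")) {
  level <- match.arg(level)
  validate_pd_matrix(pd)
  floor_cat <- if (level == "p5") "P5" else "P1"
  list(count = sum(pd$category >= floor_cat),
       total = pattern_locus_count(pd_pattern(pd)))
}
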