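#' HPA grading thresholds
#'
#' The numeric thresholds of the Hodapp-Parrish-Anderson criteria, collected
#' in one configurable object so the scheme can be adapted. Defaults are the
#' standard HPA values: mean-deviation band floors at -1, -6 and -12 dB; a
#' central point counts as depressed below 15 dB and triggers the severe rule
#' at 0 dB; the P < 5% proportion bands end at 25% and 50% (inclusive); the
#' P < 1% bands are bounded by 10/76 and 20/76 (mild is strictly below 10/76,
#' severe is at or above 20/76).
#'
#' Proportion thresholds are stored as exact integer fractions
#' (`c(numerator, denominator)`) and all band comparisons are done by integer
#' cross-multiplication, so band boundaries are exact, never floating point.
#'
#' @param md_none_floor,md_mild_floor,md_moderate_floor mean-deviation band
#'   floors in dB (inclusive: `md >= md_none_floor` is no defect).
#' @param central_low dB below which a central point counts as depressed.
#' @param central_zero dB at or below which any central point is severe.
#' @param pd5_mild_max,pd5_moderate_max inclusive upper bounds of the mild and
#'   moderate P < 5% bands, as `c(num, den)` fractions.
#' @param pd1_mild_sup,pd1_moderate_sup exclusive upper bounds of the mild and
#'   moderate P < 1% bands, as `c(num, den)` fractions.
#' @return an object of class `hpa_thresholds`.
#' @examples
#' hpa_thresholds()
#' @export
hpa_thresholds <- function(md_none_floor = -1, md_mild_floor = -6,
                           md_moderate_floor = -12,
                           central_low = 15, central_zero = 0,
                           pd5_mild_max = c(1L, 4L),
                           pd5_moderate_max = c(1L, 2L),
                           pd1_mild_sup = c(10L, 76L),
                           pd1_moderate_sup = c(20L, 76L)) {
  as_frac <- function(f, name) {
    f <- as.integer(f)
    if (length(f) != 2L || anyNA(f) || f[2] <= 0L || f[1] <= 0L || f[1] >= f[2]) {
      stop(name, " must be a fraction c(num, den) strictly between 0 and 1",
           call. = FALSE)
    }
    f
  }
  thr <- list(
    md_none_floor = md_none_floor, md_mild_floor = md_mild_floor,
    md_moderate_floor = md_moderate_floor,
    central_low = central_low, central_zero = central_zero,
    pd5_mild_max = as_frac(pd5_mild_max, "pd5_mild_max"),
    pd5_moderate_max = as_frac(pd5_moderate_max, "pd5_moderate_max"),
    pd1_mild_sup = as_frac(pd1_mild_sup, "pd1_mild_sup"),
    pd1_moderate_sup = as_frac(pd1_moderate_sup, "pd1_moderate_sup")
  )
  if (!(thr$md_none_floor > thr$md_mild_floor &&
        thr$md_mild_floor > thr$md_moderate_floor)) {
    stop("mean-deviation floors must be strictly decreasing", call. = FALSE)
  }
  if (thr$central_zero >= thr$central_low) {
    stop("central_zero must be below central_low", call. = FALSE)
  }
  frac_lt <- function(a, b) a[1] * b[2] < b[1] * a[2]
  if (!frac_lt(thr$pd5_mild_max, thr$pd5_moderate_max) ||
      !frac_lt(thr$pd1_mild_sup, thr$pd1_moderate_sup)) {
    stop("proportion thresholds must be strictly increasing", call. = FALSE)
  }
  structure(thr, class = "hpa_thresholds")
}

#' @export
print.hpa_thresholds <- function(x, ...) {
  cat("<hpa_thresholds>\n",
      "  MD floors (dB): none >= ", x$md_none_floor,
      ", mild >= ", x$md_mild_floor, ", moderate >= ", x$md_moderate_floor, "\n",
      "  central: depressed < ", x$central_low, " dB, severe <= ",
      x$central_zero, " dB\n",
      "  P<5%: mild <= ", x$pd5_mild_max[1], "/", x$pd5_mild_max[2],
      ", moderate <= ", x$pd5_moderate_max[1], "/", x$pd5_moderate_max[2], "\n",
      "  P<1%: mild < ", x$pd1_mild_sup[1], "/", x$pd1_mild_sup[2],
      ", moderate < ", x$pd1_moderate_sup[1], "/", x$pd1_moderate_sup[2], "\n",
      sep = "")
  invisible(x)
}

#' Grade mean deviation
#'
#' MD at or above -1 dB is no defect; down to -6 dB mild; down to -12 dB
#' moderate; below -12 dB severe (band floors inclusive).
#'
#' @param md mean deviation in dB (vectorised).
#' @param thresholds an [hpa_thresholds()] object.
#' @return severity grades, one per input.
#' @examples
#' grade_md(c(0, -6, -12.5))
#' @export
grade_md <- function(md, thresholds = hpa_thresholds()) {
  if (!is.numeric(md) || any(!is.finite(md))) {
    stop("md must be finite numeric (dB)", call. = FALSE)
  }
  g <- dplyr::case_when(
    md >= thresholds$md_none_floor ~ "none",
    md >= thresholds$md_mild_floor ~ "mild",
    md >= thresholds$md_moderate_floor ~ "moderate",
    TRUE ~ "severe"
  )
  severity_grade(g)
}

#' Grade the four central global-plot points
#'
#' The central 5-degree rule reads the four innermost global-plot
#' sensitivities (one per quadrant, at x,y = +/-3 degrees). All points above
#' 15 dB is no defect; depressed points confined to one hemifield is
#' moderate; depressed points in both hemifields, or any point at 0 dB, is
#' severe.
#'
#' @param central a data frame with columns `x`, `y` (degrees, one point per
#'   quadrant) and `db` (sensitivity in dB), or a plain numeric vector of
#'   four sensitivities in quadrant order (upper-nasal, upper-temporal,
#'   lower-nasal, lower-temporal).
#' @inheritParams grade_md
#' @examples
#' grade_central(c(20, 20, 20, 20))
#' grade_central(data.frame(x = c(-3, 3, -3, 3), y = c(3, 3, -3, -3),
#'                          db = c(12, 20, 20, 20)))
#' @export
grade_central <- function(central, thresholds = hpa_thresholds()) {
  central <- as_central_points(central)
  db <- central$db
  if (any(db <= thresholds$central_zero)) return(severity_grade("severe"))
  depressed <- db < thresholds$central_low
  if (!any(depressed)) return(severity_grade("none"))
  upper <- central$y > 0
  if (any(depressed & upper) && any(depressed & !upper)) {
    return(severity_grade("severe"))
  }
  severity_grade("moderate")
}

#' @rdname grade_central
#' @export
as_central_points <- function(central) {
  if (is.numeric(central) && is.null(dim(central))) {
    if (length(central) != 4L) {
      stop("central must supply exactly four sensitivities", call. = FALSE)
    }
    central <- tibble::tibble(x = c(-3, 3, -3, 3), y = c(3, 3, -3, -3),
                              db = as.numeric(central))
  }
  stopifnot(is.data.frame(central), all(c("x", "y", "db") %in% names(central)))
  central <- tibble::as_tibble(central[, c("x", "y", "db")])
  if (nrow(central) != 4L) {
    stop("central must have exactly four points", call. = FALSE)
  }
  if (!all(abs(central$x) == 3 & abs(central$y) == 3)) {
    stop("central points must lie at x, y = +/-3 degrees", call. = FALSE)
  }
  quad <- paste(sign(central$x), sign(central$y))
  if (anyDuplicated(quad)) {
    stop("central points must cover each quadrant exactly once", call. = FALSE)
  }
  if (any(!is.finite(central$db))) {
    stop("central sensitivities must be finite (dB)", call. = FALSE)
  }
  central
}

# exact rational comparisons: count/total vs num/den by cross-multiplication
frac_le <- function(count, total, frac) count * frac[2] <= frac[1] * total
frac_lt <- function(count, total, frac) count * frac[2] < frac[1] * total

check_count <- function(count, total) {
  count <- as.integer(count)
  total <- as.integer(total)
  if (anyNA(count) || anyNA(total) || any(total <= 0L) ||
      any(count < 0L) || any(count > total)) {
    stop("need 0 <= count <= total with total > 0", call. = FALSE)
  }
  list(count = count, total = total)
}

#' Grade the proportion of loci depressed below P < 5%
#'
#' No loci depressed is no defect; up to 25% (inclusive) is mild; up to 50%
#' (inclusive) moderate; above 50% severe. Comparisons are exact integer
#' cross-multiplications, so e.g. 19/76 is exactly the mild boundary.
#'
#' @param count number of loci depressed at the level (vectorised).
#' @param total number of loci in the pattern (54 or 76; vectorised).
#' @inheritParams grade_md
#' @examples
#' grade_pd5(c(0, 19, 38, 39), 76)
#' @export
grade_pd5 <- function(count, total, thresholds = hpa_thresholds()) {
  ct <- check_count(count, total)
  g <- dplyr::case_when(
    ct$count == 0L ~ "none",
    frac_le(ct$count, ct$total, thresholds$pd5_mild_max) ~ "mild",
    frac_le(ct$count, ct$total, thresholds$pd5_moderate_max) ~ "moderate",
    TRUE ~ "severe"
  )
  severity_grade(g)
}

#' Grade the proportion of loci depressed below P < 1%
#'
#' No loci is no defect; strictly below 10/76 of loci is mild; below 20/76
#' moderate; at or above 20/76 severe. Proportions (not absolute counts) are
#' used so the rule transfers between the 54-locus and 76-locus patterns;
#' comparisons are exact integer cross-multiplications.
#'
#' @inheritParams grade_pd5
#' @examples
#' grade_pd1(c(9, 10, 20), 76)
#' grade_pd1(7, 54)  # 7/54 < 10/76, still mild
#' @export
grade_pd1 <- function(count, total, thresholds = hpa_thresholds()) {
  ct <- check_count(count, total)
  g <- dplyr::case_when(
    ct$count == 0L ~ "none",
    frac_lt(ct$count, ct$total, thresholds$pd1_mild_sup) ~ "mild",
    frac_lt(ct$count, ct$total, thresholds$pd1_moderate_sup) ~ "moderate",
    TRUE ~ "severe"
  )
  severity_grade(g)
}
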