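#' A single eye's perimetry result
#'
#' Bundles the three grader inputs: mean deviation, the four central
#' global-plot sensitivities, and the pattern-deviation matrix.
#'
#' @param eye `"right"` or `"left"`.
#' @param md mean deviation in dB.
#' @param central central sensitivities, see [grade_central()].
#' @param pd a [pd_matrix()].
#' @return an object of class `field_record`.
#' @examples
#' field_record("right", md = -3.5, central = c(20, 22, 19, 21),
#'              pd = pd_matrix("24-2"))
#' @export
field_record <- function(eye, md, central, pd) {
  if (!is.numeric(md) || length(md) != 1L || !is.finite(md)) {
    stop("md must be a single finite number (dB)", call. = FALSE)
  }
  rec <- structure(
    list(eye = match_eye(eye), md = as.numeric(md),
         central = as_central_points(central), pd = validate_pd_matrix(pd)),
    class = "field_record"
  )
  rec
}

#' @export
print.field_record <- function(x, ...) {
  cat("<field_record> ", x$eye, " eye, ", pd_pattern(x$pd), ", MD ",
      format(x$md), " dB, central ", paste(x$central$db, collapse = "/"),
      " dB\n", sep = "")
  invisible(x)
}

#' Grade one perimetry result on the HPA scale
#'
#' Applies the four HPA criteria — mean deviation, central points, and the
#' two pattern-deviation proportions — and combines them by taking the most
#' severe result as the overall grading.
#'
#' @param record a [field_record()].
#' @param thresholds an [hpa_thresholds()] object.
#' @return an object of class `graded_field` with the four per-criterion
#'   grades, the overall grade, and the depressed-locus counts; see
#'   [tidy.graded_field()] for a tabular view.
#' @examples
#' rec <- field_record("right", md = -21, central = c(20, 20, 20, 20),
#'                     pd = pd_matrix("24-2"))
#' grade_field(rec)$overall  # severe on mean deviation alone
#' @export
grade_field <- function(record, thresholds = hpa_thresholds()) {
  stopifnot(inherits(record, "field_record"))
  p5 <- count_depressed(record$pd, "p5")
  p1 <- count_depressed(record$pd, "p1")
  grades <- list(
    grade_md = grade_md(record$md, thresholds),
    grade_central = grade_central(record$central, thresholds),
    grade_pd5 = grade_pd5(p5$count, p5$total, thresholds),
    grade_pd1 = grade_pd1(p1$count, p1$total, thresholds)
  )
  structure(
    c(grades,
      list(overall = combine_grades(grades),
           counts = list(p5 = p5$count, p1 = p1$count, total = p5$total),
           thresholds = thresholds)),
    class = "graded_field"
  )
}

#' @export
print.graded_field <- function(x, ...) {
  cat("<graded_field> overall: ", as.character(x$overall), "\n",
      "  MD: ", as.character(x$grade_md),
      " | central: ", as.character(x$grade_central),
      " | P<5% (", x$counts$p5, "/", x$counts$total, "): ",
      as.character(x$grade_pd5),
      " | P<1% (", x$counts$p1, "/", x$counts$total, "): ",
      as.character(x$grade_pd1), "\n", sep = "")
  invisible(x)
}

#' @rdname grade_field
#' @param x a `graded_field`.
#' @param ... unused.
#' @export
tidy.graded_field <- function(x, ...) {
  tibble::tibble(
    grade_md = x$grade_md, grade_central = x$grade_central,
    grade_pd5 = x$grade_pd5, grade_pd1 = x$grade_pd1,
    overall = x$overall,
    n_p5 = x$counts$p5, n_p1 = x$counts$p1, n_loci = x$counts$total
  )
}

#' Grade a table of perimetry results
#'
#' Data-frame-first interface over [grade_field()]: takes a tibble with one
#' row per field (as produced by [make_validation_set()], or assembled by the
#' caller with list-columns) and appends the per-criterion and overall grades.
#'
#' @param fields a data frame with columns `eye`, `md`, `central` (list of
#'   4-point data frames or 4-vectors) and `pd` (list of [pd_matrix()]
#'   objects), or a `field` list-column of [field_record()]s.
#' @inheritParams grade_field
#' @return the input tibble with columns `grade_md`, `grade_central`,
#'   `grade_pd5`, `grade_pd1`, `overall`, `n_p5`, `n_p1`, `n_loci` appended.
#' @export
grade_fields <- function(fields, thresholds = hpa_thresholds()) {
  stopifnot(is.data.frame(fields))
  recs <- if ("field" %in% names(fields)) {
    fields$field
  } else {
    purrr::pmap(fields[, c("eye", "md", "central", "pd")],
                function(eye, md, central, pd) field_record(eye, md, central, pd))
  }
  graded <- purrr::map_dfr(recs, function(r) tidy(grade_field(r, thresholds)))
  dplyr::bind_cols(tibble::as_tibble(fields), graded)
}
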