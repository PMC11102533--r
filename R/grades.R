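#' Severity grades
#'
#' The Hodapp-Parrish-Anderson (HPA) scale stages a visual field as having no
#' defect or a mild, moderate or severe glaucomatous defect. Grades are
#' represented throughout the package as ordered factors so that "most severe
#' wins" combination is simply `max()`.
#'
#' @return `grade_levels()` returns the four level names in increasing
#'   severity; `severity_grade()` returns an ordered factor on those levels.
#' @examples
#' severity_grade(c("mild", "severe"))
#' max(severity_grade(c("none", "moderate", "mild")))
#' @export
grade_levels <- function() c("none", "mild", "moderate", "severe")

#' @param x character vector of grade names (`"early"` is accepted as an
#'   alias for `"mild"`).
#' @rdname grade_levels
#' @export
severity_grade <- function(x) {
  x <- tolower(as.character(x))
  x[x == "early"] <- "mild"
  bad <- !is.na(x) & !x %in% grade_levels()
  if (any(bad)) {
    stop("unknown severity grade(s): ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  factor(x, levels = grade_levels(), ordered = TRUE)
}

#' Combine per-criterion grades, most severe wins
#'
#' The overall HPA stage is the most severe of the per-criterion stages
#' (mean deviation, central points, and the two pattern-deviation proportions).
#'
#' @param grades a vector (or list) of severity grades.
#' @return a length-one ordered factor.
#' @examples
#' combine_grades(c("mild", "severe", "none", "moderate"))
#' @export
combine_grades <- function(grades) {
  if (is.list(grades)) grades <- unlist(lapply(grades, as.character))
  g <- severity_grade(grades)
  if (length(g) == 0L) stop("combine_grades() needs at least one grade", call. = FALSE)
  if (anyNA(g)) stop("combine_grades() cannot combine missing grades", call. = FALSE)
  max(g)
}

#' Significance categories of a pattern-deviation plot
#'
#' Each test locus of a Humphrey pattern-deviation probability plot carries one
#' of five symbols: not significant, or depressed at P < 5%, < 2%, < 1%,
#' < 0.5%. Categories are ordered by increasing significance.
#'
#' @return `pd_categories()` returns the five category names;
#'   `pd_category()` returns an ordered factor on them.
#' @examples
#' pd_category(c("NS", "P05"))
#' @export
pd_categories <- function() c("NS", "P5", "P2", "P1", "P05")

#' @param x character vector of category names.
#' @rdname pd_categories
#' @export
pd_category <- function(x) {
  x <- toupper(as.character(x))
  bad <- !is.na(x) & !x %in% pd_categories()
  if (any(bad)) {
    stop("unknown significance category(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  factor(x, levels = pd_categories(), ordered = TRUE)
}
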