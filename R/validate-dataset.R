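#' Validate the image-to-grade pipeline on a dataset
#'
#' Runs the full pipeline on every record — parse the rendered
#' pattern-deviation plot back into a matrix, combine it with the record's
#' numeric mean deviation and central points, grade with the HPA rules — and
#' compares against the ground-truth grades (the rule engine applied to the
#' numeric records). Emits the confusion matrix, Cohen's kappa, and binary
#' metrics for severe-vs-rest and any-defect-vs-none. Per-record parse
#' failures are recorded and counted, never silently dropped.
#'
#' @param ds an `hpa_dataset` from [make_validation_set()], a directory
#'   written by [write_dataset()], or a data frame with columns
#'   `record_id`, `true_grade`, `field` and either `plot` (rendered plots)
#'   or `image` (grayscale matrices).
#' @param thresholds an [hpa_thresholds()] object.
#' @return an object of class `hpa_validation`: list with `results` (tibble:
#'   record_id, truth, predicted, n_warnings), `cm`, `kappa`,
#'   `metrics_severe`, `metrics_any_defect`, `failures`.
#' @examples
#' \donttest{
#' v <- validate_dataset(make_validation_set(n = 8, seed = 1))
#' glance(v)
#' }
#' @export
validate_dataset <- function(ds, thresholds = hpa_thresholds()) {
  if (is.character(ds)) ds <- read_dataset(ds)
  stopifnot(is.data.frame(ds),
            all(c("record_id", "true_grade", "field") %in% names(ds)))
  get_image <- function(i) {
    if ("plot" %in% names(ds)) ds$plot[[i]]$image else ds$image[[i]]
  }
  failures <- character()
  rows <- purrr::map_dfr(seq_len(nrow(ds)), function(i) {
    rec <- ds$field[[i]]
    res <- tryCatch({
      pd <- parse_pattern_plot(get_image(i), pd_pattern(rec$pd), rec$eye)
      parsed_rec <- field_record(rec$eye, rec$md, rec$central, pd)
      list(predicted = as.character(grade_field(parsed_rec, thresholds)$overall),
           n_warnings = length(attr(pd, "diagnostics")$warnings))
    }, error = identity)
    if (inherits(res, "error")) {
      failures <<- c(failures,
                     paste0(ds$record_id[i], ": ", conditionMessage(res)))
      res <- list(predicted = NA_character_, n_warnings = NA_integer_)
    }
    tibble::tibble(record_id = ds$record_id[i],
                   truth = as.character(ds$true_grade[i]),
                   predicted = res$predicted, n_warnings = res$n_warnings)
  })
  ok <- !is.na(rows$predicted)
  if (!any(ok)) stop("no record could be parsed", call. = FALSE)
  cm <- confusion_matrix(rows$truth[ok], rows$predicted[ok])
  structure(
    list(results = rows, cm = cm, kappa = cohen_kappa(cm),
         metrics_severe = binary_metrics(cm, positive = "severe"),
         metrics_any_defect = binary_metrics(
           cm, positive = c("mild", "moderate", "severe")),
         failures = failures),
    class = "hpa_validation"
  )
}

#' @export
print.hpa_validation <- function(x, ...) {
  g <- glance(x)
  cat("<hpa_validation> n = ", g$n, " (", g$n_failed, " parse failures)\n",
      "  kappa = ", format_metric(g$kappa),
      ", accuracy = ", format_pct(g$accuracy), "\n",
      "  severe-vs-rest: sensitivity ", format_pct(g$sensitivity_severe),
      ", specificity ", format_pct(g$specificity_severe),
      ", F1 ", format_pct(g$f1_severe), "\n",
      "  any-defect: sensitivity ", format_pct(g$sensitivity_any),
      ", specificity ", format_pct(g$specificity_any), "\n", sep = "")
  invisible(x)
}

format_metric <- function(x) if (is.na(x)) "undefined" else sprintf("%.2f", x)
format_pct <- function(x) if (is.na(x)) "undefined" else sprintf("%.1f%%", 100 * x)

#' @rdname validate_dataset
#' @param x an `hpa_validation`.
#' @param ... unused.
#' @export
glance.hpa_validation <- function(x, ...) {
  acc_multi <- sum(diag(x$cm)) / sum(x$cm)
  tibble::tibble(
    n = nrow(x$results), n_failed = length(x$failures),
    kappa = x$kappa$kappa, accuracy = acc_multi,
    sensitivity_severe = x$metrics_severe$sensitivity,
    specificity_severe = x$metrics_severe$specificity,
    f1_severe = x$metrics_severe$f1,
    sensitivity_any = x$metrics_any_defect$sensitivity,
    specificity_any = x$metrics_any_defect$specificity
  )
}

#' @rdname validate_dataset
#' @export
tidy.hpa_validation <- function(x, ...) x$results

#' Write a validation report as JSON
#'
#' Serialises the confusion matrix, kappa and binary metrics; undefined
#' metrics are written as the string `"undefined"` (the convention used when
#' a denominator is empty), never as 0.
#'
#' @param v an `hpa_validation`.
#' @param path file path.
#' @export
write_validation_json <- function(v, path) {
  stopifnot(inherits(v, "hpa_validation"))
  und <- function(x) if (is.na(x)) "undefined" else x
  metr <- function(m) list(sensitivity = und(m$sensitivity),
                           specificity = und(m$specificity),
                           accuracy = und(m$accuracy), f1 = und(m$f1),
                           tp = m$tp, fp = m$fp, fn = m$fn, tn = m$tn)
  obj <- list(
    n = nrow(v$results), n_failed = length(v$failures),
    confusion_matrix = list(classes = rownames(v$cm),
                            counts = unclass(v$cm)),
    kappa = und(v$kappa$kappa),
    severe_vs_rest = metr(v$metrics_severe),
    any_defect_vs_none = metr(v$metrics_any_defect),
    failures = v$failures
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
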