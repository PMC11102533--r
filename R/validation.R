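#' Confusion matrix of truth vs predicted grades
#'
#' @param truth,predicted equal-length vectors of grade labels.
#' @param classes ordered class labels; both inputs must be subsets.
#' @return a `confusion_matrix`: an integer matrix (rows = truth,
#'   columns = predicted) with the class vector attached.
#' @examples
#' confusion_matrix(c("mild", "mild", "severe"), c("mild", "severe", "severe"),
#'                  classes = c("mild", "severe"))
#' @export
confusion_matrix <- function(truth, predicted, classes = grade_levels()) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted) || length(truth) == 0L) {
    stop("truth and predicted must be non-empty and equal length", call. = FALSE)
  }
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad)) {
    stop("labels outside classes: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  tab <- table(factor(truth, levels = classes),
               factor(predicted, levels = classes))
  m <- matrix(as.integer(tab), nrow = length(classes),
              dimnames = list(truth = classes, predicted = classes))
  structure(m, class = c("confusion_matrix", "matrix"))
}

as_cm <- function(x, classes = NULL) {
  if (inherits(x, "confusion_matrix")) return(x)
  x <- as.matrix(x)
  if (nrow(x) != ncol(x)) stop("confusion matrix must be square", call. = FALSE)
  if (any(x < 0) || sum(x) == 0) {
    stop("confusion matrix needs non-negative counts with a positive total",
         call. = FALSE)
  }
  if (is.null(classes)) {
    classes <- rownames(x)
    if (is.null(classes)) classes <- paste0("class", seq_len(nrow(x)))
  }
  dimnames(x) <- list(truth = classes, predicted = classes)
  structure(x, class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> n =", sum(x), "\n")
  print(unclass(x))
  invisible(x)
}

#' @rdname confusion_matrix
#' @param x a `confusion_matrix`.
#' @param ... unused.
#' @export
tidy.confusion_matrix <- function(x, ...) {
  df <- as.data.frame(as.table(unclass(x)), stringsAsFactors = FALSE)
  names(df) <- c("truth", "predicted", "n")
  tibble::as_tibble(df)
}

#' Binary detection metrics with explicit undefined semantics
#'
#' Collapses a multi-class confusion matrix to positive-vs-rest and computes
#' sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy and
#' F1 = 2TP/(2TP+FP+FN). A metric whose denominator is zero is reported as
#' `NA` with `FALSE` in the matching `*_defined` flag — undefined is a
#' first-class outcome, distinct from zero (a dataset with no
#' defect-free fields has no true negatives for any-defect detection, so its
#' specificity is undefined, not 0 or 1).
#'
#' @param cm a [confusion_matrix()] (or plain square matrix).
#' @param positive character vector of class labels counted as positive; a
#'   non-empty proper subset of the classes.
#' @return a one-row tibble: `tp`, `fp`, `fn`, `tn`, `sensitivity`,
#'   `specificity`, `accuracy`, `f1` and the four `*_defined` flags.
#' @examples
#' cm <- confusion_matrix(rep(c("mild", "severe"), c(5, 5)),
#'                        rep(c("mild", "severe"), c(5, 5)))
#' binary_metrics(cm, positive = "severe")
#' @export
binary_metrics <- function(cm, positive) {
  cm <- as_cm(cm)
  classes <- rownames(cm)
  positive <- as.character(positive)
  if (length(positive) == 0L || !all(positive %in% classes) ||
      length(setdiff(classes, positive)) == 0L) {
    stop("positive must be a non-empty proper subset of the classes",
         call. = FALSE)
  }
  pos <- classes %in% positive
  tp <- sum(cm[pos, pos]); fn <- sum(cm[pos, !pos])
  fp <- sum(cm[!pos, pos]); tn <- sum(cm[!pos, !pos])
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  acc <- ratio(tp + tn, tp + fp + fn + tn)
  f1 <- ratio(2 * tp, 2 * tp + fp + fn)
  tibble::tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = sens, specificity = spec, accuracy = acc, f1 = f1,
    sensitivity_defined = !is.na(sens), specificity_defined = !is.na(spec),
    accuracy_defined = !is.na(acc), f1_defined = !is.na(f1)
  )
}

#' Cohen's kappa
#'
#' Unweighted chance-corrected agreement:
#' `kappa = (p_o - p_e) / (1 - p_e)` with `p_o` the observed diagonal
#' proportion and `p_e` the expected agreement from the row and column
#' margins. When `p_e = 1` (a single occupied margin on both sides) kappa is
#' undefined and reported as `NA` with `kappa_defined = FALSE`.
#'
#' @param cm a [confusion_matrix()], or a truth vector (with `predicted`).
#' @param predicted optional predicted labels when `cm` is a truth vector.
#' @param classes class labels when building from label vectors.
#' @return a one-row tibble: `kappa`, `p_observed`, `p_expected`, `n`,
#'   `kappa_defined`.
#' @examples
#' cohen_kappa(matrix(c(45, 5, 5, 45), 2, byrow = TRUE))  # 0.80
#' @export
cohen_kappa <- function(cm, predicted = NULL, classes = grade_levels()) {
  if (!is.null(predicted)) cm <- confusion_matrix(cm, predicted, classes)
  cm <- as_cm(cm)
  n <- sum(cm)
  p_o <- sum(diag(cm)) / n
  p_e <- sum((rowSums(cm) / n) * (colSums(cm) / n))
  kappa <- if (abs(1 - p_e) < .Machine$double.eps^0.5) NA_real_
           else (p_o - p_e) / (1 - p_e)
  tibble::tibble(kappa = kappa, p_observed = p_o, p_expected = p_e,
                 n = n, kappa_defined = !is.na(kappa))
}

#' Two-sample t-test from summary statistics
#'
#' Compares two groups given only mean, SD and n per group:
#' `t = (mean_x - mean_y) / sqrt(sd_x^2/n_x + sd_y^2/n_y)` with
#' Welch-Satterthwaite degrees of freedom by default (appropriate when the
#' spreads differ a lot, as between a constrained tool-assisted workflow and
#' free-form manual appraisal), or the pooled-variance Student form. With
#' equal group sizes the two t statistics coincide; only the degrees of
#' freedom (hence p) differ.
#'
#' @param mean_x,sd_x,n_x,mean_y,sd_y,n_y group summaries (sd >= 0, n >= 2).
#' @param var_equal use the pooled-variance Student form?
#' @return a one-row tibble: `estimate` (mean_x - mean_y), `statistic`,
#'   `parameter` (df), `p_value`, `method`. `statistic` is `NA` (undefined)
#'   when both SDs are zero and the means are equal.
#' @examples
#' t_test_summary(26.5, 3.3, 20, 48.6, 28.4, 20)  # t = -3.46, p = 0.003
#' @export
t_test_summary <- function(mean_x, sd_x, n_x, mean_y, sd_y, n_y,
                           var_equal = FALSE) {
  stopifnot(sd_x >= 0, sd_y >= 0, n_x >= 2, n_y >= 2)
  est <- mean_x - mean_y
  if (var_equal) {
    df <- n_x + n_y - 2
    sp2 <- ((n_x - 1) * sd_x^2 + (n_y - 1) * sd_y^2) / df
    se <- sqrt(sp2 * (1 / n_x + 1 / n_y))
    method <- "Two-sample t-test (pooled variance)"
  } else {
    vx <- sd_x^2 / n_x; vy <- sd_y^2 / n_y
    se <- sqrt(vx + vy)
    df <- if (se == 0) NA_real_ else
      (vx + vy)^2 / (vx^2 / (n_x - 1) + vy^2 / (n_y - 1))
    method <- "Welch two-sample t-test"
  }
  if (se == 0) {
    t <- if (est == 0) NA_real_ else sign(est) * Inf
    p <- if (est == 0) NA_real_ else 0
  } else {
    t <- est / se
    p <- 2 * stats::pt(-abs(t), df)
  }
  tibble::tibble(estimate = est, statistic = t, parameter = df,
                 p_value = p, method = method)
}
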