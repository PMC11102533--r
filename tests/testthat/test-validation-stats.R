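test_that("confusion_matrix counts truth-by-predicted cells", {
  cm <- confusion_matrix(c("mild", "mild", "severe"), c("mild", "severe", "severe"),
                         classes = c("mild", "severe"))
  expect_equal(unclass(cm),
               matrix(c(1L, 0L, 1L, 1L), 2,
                      dimnames = list(truth = c("mild", "severe"),
                                      predicted = c("mild", "severe"))))
  # identical lists give a diagonal matrix
  set.seed(4)
  lab <- sample(grade_levels(), 30, replace = TRUE)
  cm2 <- confusion_matrix(lab, lab)
  expect_equal(sum(cm2) , 30)
  expect_equal(sum(diag(cm2)), 30)
  expect_error(confusion_matrix("mild", c("mild", "severe")), "equal length")
  expect_error(confusion_matrix("mild", "huge"), "classes")
  expect_equal(sum(tidy(cm)$n), 3)
})

test_that("binary metrics match hand-evaluated formulas", {
  cm <- matrix(c(5, 2, 1, 10), 2, byrow = TRUE,
               dimnames = list(c("pos", "neg"), c("pos", "neg")))
  m <- binary_metrics(cm, positive = "pos")
  expect_equal(m$sensitivity, 5 / 7)
  expect_equal(m$specificity, 10 / 11)
  expect_equal(m$f1, 10 / 13)
  expect_equal(m$accuracy, 15 / 18)
})

test_that("zero denominators yield undefined metrics, not 0 or 1", {
  # no defect-free fields: no true negatives, no false positives
  cm <- confusion_matrix(rep(c("mild", "severe"), 5),
                         rep(c("mild", "severe"), 5))
  m <- binary_metrics(cm, positive = c("mild", "moderate", "severe"))
  expect_true(is.na(m$specificity))
  expect_false(m$specificity_defined)
  expect_equal(m$sensitivity, 1)
  expect_true(m$sensitivity_defined)
  expect_error(binary_metrics(cm, positive = grade_levels()), "proper subset")
})

test_that("cohen_kappa reproduces closed-form cases", {
  expect_equal(cohen_kappa(matrix(c(45, 5, 5, 45), 2, byrow = TRUE))$kappa, 0.80)
  expect_equal(cohen_kappa(matrix(c(25, 25, 25, 25), 2))$kappa, 0)
  set.seed(8)
  lab <- sample(c("mild", "moderate", "severe"), 40, replace = TRUE)
  k <- cohen_kappa(lab, lab)
  expect_equal(k$kappa, 1)
  # kappa = 1 iff off-diagonal mass is zero
  cm <- confusion_matrix(lab, c(lab[-1], "mild"))
  expect_lt(cohen_kappa(cm)$kappa, 1)
  # permutation invariance
  m <- matrix(c(20, 3, 1, 2, 15, 4, 0, 2, 9), 3, byrow = TRUE)
  perm <- c(3, 1, 2)
  expect_equal(cohen_kappa(m)$kappa, cohen_kappa(m[perm, perm])$kappa)
  # degenerate single-margin table
  expect_true(is.na(cohen_kappa(matrix(c(12, 0, 0, 0), 2))$kappa))
})

test_that("kappa and metrics agree with brute force on random label lists", {
  set.seed(123)
  lv <- grade_levels()
  for (i in 1:1000) {
    n <- sample(4:25, 1)
    truth <- sample(lv, n, replace = TRUE)
    pred <- sample(lv, n, replace = TRUE)
    cm <- confusion_matrix(truth, pred)
    expect_equal(sum(cm), n)
    expect_equal(unname(rowSums(cm)),
                 unname(vapply(lv, function(g) sum(truth == g), 0)))

    # brute-force kappa from the raw lists
    p_o <- mean(truth == pred)
    p_e <- sum(vapply(lv, function(g) mean(truth == g) * mean(pred == g), 0))
    k <- cohen_kappa(cm)
    if (abs(1 - p_e) < 1e-12) {
      expect_true(is.na(k$kappa))
    } else {
      expect_equal(k$kappa, (p_o - p_e) / (1 - p_e))
    }

    # brute-force recount of the severe-vs-rest collapse
    m <- binary_metrics(cm, positive = "severe")
    tp <- sum(truth == "severe" & pred == "severe")
    fn <- sum(truth == "severe" & pred != "severe")
    fp <- sum(truth != "severe" & pred == "severe")
    tn <- sum(truth != "severe" & pred != "severe")
    expect_equal(c(m$tp, m$fn, m$fp, m$tn), c(tp, fn, fp, tn))
    expect_equal(m$sensitivity, if (tp + fn == 0) NA_real_ else tp / (tp + fn))
    expect_equal(m$specificity, if (tn + fp == 0) NA_real_ else tn / (tn + fp))
    expect_equal(m$f1,
                 if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn))
  }
})

test_that("kappa matches an independent implementation on random tables", {
  set.seed(42)
  for (i in 1:50) {
    m <- matrix(rpois(9, 8), 3)
    if (sum(m) == 0) next
    expect_equal(cohen_kappa(m)$kappa,
                 e1071::classAgreement(m)$kappa, tolerance = 1e-12)
  }
})

test_that("summary t-test matches stats::t.test on reconstructed samples", {
  make_exact <- function(n, mean, sd) {
    x <- scale(rnorm(n))[, 1]
    x * sd + mean
  }
  set.seed(5)
  for (i in 1:20) {
    n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
    m1 <- runif(1, -10, 60); m2 <- runif(1, -10, 60)
    s1 <- runif(1, 0.5, 25); s2 <- runif(1, 0.5, 25)
    a <- make_exact(n1, m1, s1); b <- make_exact(n2, m2, s2)
    ours <- t_test_summary(m1, s1, n1, m2, s2, n2)
    ref <- stats::t.test(a, b)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(ours$parameter, unname(ref$parameter), tolerance = 1e-8)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-8)
    ours_p <- t_test_summary(m1, s1, n1, m2, s2, n2, var_equal = TRUE)
    ref_p <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(ours_p$statistic, unname(ref_p$statistic), tolerance = 1e-8)
    expect_equal(ours_p$p_value, ref_p$p.value, tolerance = 1e-8)
  }
})

test_that("Welch and pooled t coincide with equal n and equal sd", {
  for (m1 in c(10, 25)) for (sd in c(2, 7)) for (n in c(8, 20)) {
    w <- t_test_summary(m1, sd, n, 18, sd, n)
    p <- t_test_summary(m1, sd, n, 18, sd, n, var_equal = TRUE)
    expect_equal(w$statistic, p$statistic)
    expect_equal(w$parameter, p$parameter)  # Welch df reduces to 2n - 2
  }
  z <- t_test_summary(5, 0, 10, 5, 0, 10)
  expect_true(is.na(z$statistic))
})

test_that("identical summaries give t = 0", {
  res <- t_test_summary(26.5, 3.3, 20, 26.5, 3.3, 20)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})
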