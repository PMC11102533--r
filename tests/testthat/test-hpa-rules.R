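test_that("mean-deviation bands follow the HPA floors, boundaries inclusive", {
  expect_equal(as.character(grade_md(0)), "none")
  expect_equal(as.character(grade_md(-1)), "none")
  expect_equal(as.character(grade_md(-1.01)), "mild")
  expect_equal(as.character(grade_md(-6)), "mild")
  expect_equal(as.character(grade_md(-12)), "moderate")
  expect_equal(as.character(grade_md(-12.5)), "severe")
  expect_equal(as.character(grade_md(-21)), "severe")
  expect_error(grade_md(NA_real_), "finite")
  expect_error(grade_md(Inf), "finite")
})

test_that("central 5-degree rule: hemifield logic and the 0 dB override", {
  g <- function(db4) as.character(grade_central(db4))
  expect_equal(g(c(20, 20, 20, 20)), "none")
  expect_equal(g(c(16, 16, 16, 16)), "none")           # strictly > 15 is intact
  expect_equal(g(c(12, 20, 20, 20)), "moderate")       # upper hemifield only
  expect_equal(g(c(20, 20, 10, 14)), "moderate")       # lower hemifield only
  expect_equal(g(c(12, 20, 10, 20)), "severe")         # both hemifields
  expect_equal(g(c(0, 20, 20, 20)), "severe")          # any point at 0 dB
  expect_equal(g(c(20, 20, 20, -1)), "severe")         # below zero still severe
  expect_equal(g(c(15, 20, 20, 20)), "none")           # depressed means strictly < 15
  expect_equal(g(c(14.9, 20, 20, 20)), "moderate")
  expect_error(grade_central(c(20, 20, 20)), "four")
  expect_error(grade_central(
    data.frame(x = c(-3, -3, -3, 3), y = c(3, 3, -3, -3), db = rep(20, 4))),
    "quadrant")
})

test_that("P<5% proportion bands are exact at the printed boundaries", {
  expect_equal(as.character(grade_pd5(0, 76)), "none")
  expect_equal(as.character(grade_pd5(19, 76)), "mild")      # exactly 25%
  expect_equal(as.character(grade_pd5(20, 76)), "moderate")
  expect_equal(as.character(grade_pd5(38, 76)), "moderate")  # exactly 50%
  expect_equal(as.character(grade_pd5(39, 76)), "severe")
  expect_equal(as.character(grade_pd5(13, 54)), "mild")      # 13/54 < 1/4
  expect_equal(as.character(grade_pd5(14, 54)), "moderate")  # 14/54 > 1/4
  expect_error(grade_pd5(55, 54), "count")
})

test_that("P<1% proportion bands use the 10/76 and 20/76 boundaries", {
  expect_equal(as.character(grade_pd1(0, 76)), "none")
  expect_equal(as.character(grade_pd1(9, 76)), "mild")
  expect_equal(as.character(grade_pd1(10, 76)), "moderate")
  expect_equal(as.character(grade_pd1(19, 76)), "moderate")
  expect_equal(as.character(grade_pd1(20, 76)), "severe")
  # cross-schema rational comparison: 7/54 = 0.1296 < 10/76 = 0.1316
  expect_equal(as.character(grade_pd1(7, 54)), "mild")
  expect_equal(as.character(grade_pd1(8, 54)), "moderate")
  expect_error(grade_pd1(-1, 54), "count")
})

test_that("exhaustive band sweep agrees with the independent oracle", {
  for (total in c(54L, 76L)) {
    for (count in 0:total) {
      expect_equal(as.character(grade_pd5(count, total)),
                   oracle_pd5(count, total),
                   info = sprintf("pd5 %d/%d", count, total))
      expect_equal(as.character(grade_pd1(count, total)),
                   oracle_pd1(count, total),
                   info = sprintf("pd1 %d/%d", count, total))
    }
  }
  for (md in seq(-30, 2, by = 0.1)) {
    expect_equal(as.character(grade_md(md)), oracle_md(md))
  }
})

test_that("count_depressed counts category unions over the right denominator", {
  pd <- pd_with_counts("24-2", 10, 3, weak = "P5", strong = "P05")
  expect_equal(count_depressed(pd, "p5"), list(count = 10L, total = 54L))
  expect_equal(count_depressed(pd, "p1"), list(count = 3L, total = 54L))
  empty <- pd_matrix("24-2")
  expect_equal(count_depressed(empty, "p5"), list(count = 0L, total = 54L))
  mixed <- pd_with_counts("30-2", 12, 5, weak = "P2", strong = "P1")
  expect_equal(count_depressed(mixed, "p5")$count, 12L)
  expect_equal(count_depressed(mixed, "p1")$count, 5L)
})

test_that("combine_grades is the maximum under the severity order", {
  expect_equal(as.character(combine_grades(rep("none", 4))), "none")
  expect_equal(as.character(combine_grades(c("mild", "severe", "none", "moderate"))),
               "severe")
  expect_equal(as.character(combine_grades("moderate")), "moderate")
  expect_error(combine_grades(character()), "at least one")
  # brute force over all 4^4 combinations
  lv <- grade_levels()
  grid <- expand.grid(a = lv, b = lv, c = lv, d = lv, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    g <- unlist(grid[i, ])
    expect_equal(as.character(combine_grades(g)),
                 lv[max(match(g, lv))])
  }
})

test_that("grade_field composes the four criteria, most severe wins", {
  gf <- grade_field(healthy_record())
  expect_equal(as.character(gf$overall), "none")

  # the 1% criterion dominates a mild mean deviation
  rec <- field_record("right", -3, healthy_central(),
                      pd_with_counts("30-2", 20, 20, strong = "P1"))
  gf <- grade_field(rec)
  expect_equal(as.character(gf$grade_md), "mild")
  expect_equal(as.character(gf$grade_pd1), "severe")
  expect_equal(as.character(gf$overall), "severe")

  # mean deviation alone suffices
  gf <- grade_field(field_record("right", -21, healthy_central(),
                                 pd_matrix("24-2")))
  expect_equal(as.character(gf$overall), "severe")

  # purity: identical inputs, identical outputs
  gf2 <- grade_field(field_record("right", -21, healthy_central(),
                                  pd_matrix("24-2")))
  expect_identical(tidy(gf), tidy(gf2))
  expect_equal(as.character(gf$overall),
               as.character(combine_grades(c(gf$grade_md, gf$grade_central,
                                             gf$grade_pd5, gf$grade_pd1))))
})

test_that("overall grade is monotone in MD and in depressed counts", {
  pd <- pd_with_counts("24-2", 5, 1)
  grades <- vapply(seq(2, -30, by = -0.1), function(md) {
    as.character(grade_field(field_record("right", md, c(20, 18, 20, 16), pd))$overall)
  }, "")
  ranks <- match(grades, grade_levels())
  expect_true(all(diff(ranks) >= 0))

  # adding a depressed point never decreases the overall grade
  for (total in c(54L, 76L)) {
    r5 <- match(vapply(0:total, function(k) oracle_pd5(k, total), ""), grade_levels())
    r1 <- match(vapply(0:total, function(k) oracle_pd1(k, total), ""), grade_levels())
    expect_true(all(diff(r5) >= 0))
    expect_true(all(diff(r1) >= 0))
  }
})

test_that("thresholds are configurable and validated", {
  thr <- hpa_thresholds(md_none_floor = -2)
  expect_equal(as.character(grade_md(-1.5, thr)), "none")
  expect_error(hpa_thresholds(md_mild_floor = -13), "decreasing")
  expect_error(hpa_thresholds(pd5_mild_max = c(3L, 4L), pd5_moderate_max = c(1L, 2L)),
               "increasing")
  expect_error(hpa_thresholds(pd1_mild_sup = c(0L, 76L)), "fraction")
  # severity labels accept the historical "early" alias
  expect_equal(as.character(severity_grade("early")), "mild")
})
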