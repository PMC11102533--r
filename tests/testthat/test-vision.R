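test_that("plot bounds are recovered within 2 px of the rendered geometry", {
  for (pat in c("24-2", "30-2")) for (eye in c("right", "left")) {
    rp <- render_pattern_plot(random_pd(pat), eye, render_style(cell_px = 32),
                              seed = 3)
    g <- detect_plot_bounds(rp$image, pat, eye)
    truth <- rp$geometry
    expect_lt(abs(g$left - truth$left), 2.5)
    expect_lt(abs(g$right - truth$right), 2.5)
    expect_lt(abs(g$top - truth$top), 2.5)
    expect_lt(abs(g$bottom - truth$bottom), 2.5)
    expect_lt(abs(g$ppd_x - truth$ppd_x) / truth$ppd_x, 0.02)
  }
})

test_that("degenerate and ambiguous images raise informative errors", {
  expect_error(detect_plot_bounds(matrix(1, 50, 50), "24-2", "right"),
               "no plot found")
  rp <- render_pattern_plot(pd_matrix("24-2"), "right", seed = 1)
  two <- cbind(rp$image, matrix(1, nrow(rp$image), 15), rp$image)
  expect_error(detect_plot_bounds(two, "24-2", "right"), "ambiguous")
})

test_that("map_loci yields one in-bounds centre per locus, mirrored by eye", {
  rp <- render_pattern_plot(pd_matrix("30-2"), "right", seed = 1)
  g <- rp$geometry
  right <- map_loci(g, "30-2", "right")
  left <- map_loci(g, "30-2", "left")
  expect_equal(nrow(right), 76L)
  expect_equal(nrow(map_loci(
    render_pattern_plot(pd_matrix("24-2"), "right", seed = 1)$geometry,
    "24-2", "right")), 54L)
  # reflection about the vertical line through the origin
  expect_equal(sort(right$col - g$origin_col), sort(g$origin_col - left$col),
               tolerance = 1e-9)
  expect_equal(right$row, left$row)
  # sampling windows of distinct loci do not overlap at 0.8x pitch
  pitch <- 6 * g$ppd_x
  d <- as.matrix(stats::dist(cbind(right$row, right$col)))
  diag(d) <- Inf
  expect_gt(min(d), 0.8 * pitch)
  # a shrunken geometry puts centres outside a tiny image
  g_bad <- plot_geometry(1, 1, 50, 50, origin_row = 25, origin_col = 25,
                         ppd_x = 5, ppd_y = 5, img_dim = c(40, 40))
  expect_error(map_loci(g_bad, "30-2", "right"), "geometry error")
})

test_that("every glyph classifies to its own category at several scales", {
  for (fam in glyph_families()) {
    for (cell in c(24L, 32L, 48L)) {
      for (cat in pd_categories()) {
        mask <- glyph_mask(cat, cell, fam)
        res <- classify_symbol(mask, (cell + 1) / 2, (cell + 1) / 2, cell)
        expect_equal(as.character(res$category), cat,
                     info = sprintf("%s at %d px (%s)", cat, cell, fam))
      }
    }
  }
})

test_that("glyph ink density increases with significance in both families", {
  for (fam in glyph_families()) {
    fr <- vapply(pd_categories(), function(cat) mean(glyph_mask(cat, 48, fam)),
                 0)
    expect_true(all(diff(fr) > 0), info = fam)
  }
  expect_error(glyph_mask("P5", 12), "at least 16")
})

test_that("an empty sampling window is an error; an inkless one maps to NS", {
  ink <- matrix(FALSE, 40, 40)
  expect_error(classify_symbol(ink, 500, 500, 32), "outside")
  res <- classify_symbol(ink, 20, 20, 32)
  expect_equal(as.character(res$category), "NS")
})

test_that("parse is idempotent and invariant to white margins", {
  pd <- random_pd("24-2")
  rp <- render_pattern_plot(pd, "right", seed = 11)
  p1 <- parse_pattern_plot(rp$image, "24-2", "right")
  p2 <- parse_pattern_plot(rp$image, "24-2", "right")
  expect_identical(as.character(p1$category), as.character(p2$category))
  expect_identical(as.character(p1$category), as.character(pd$category))
  for (padpx in c(3, 10, 20)) {
    p3 <- parse_pattern_plot(pad_image(rp$image, padpx), "24-2", "right")
    expect_identical(as.character(p3$category), as.character(pd$category),
                     info = paste("pad", padpx))
  }
})

test_that("parse recovers a frameless plot via grid refinement", {
  set.seed(21)
  for (pat in c("24-2", "30-2")) {
    pd <- random_pd(pat)
    rp <- render_pattern_plot(pd, "left",
                              render_style(cell_px = 32, frame = FALSE),
                              seed = 2)
    parsed <- parse_pattern_plot(rp$image, pat, "left")
    expect_identical(as.character(parsed$category), as.character(pd$category))
  }
})

test_that("parser output carries geometry and per-locus diagnostics", {
  pd <- pd_with_counts("24-2", 8, 2)
  rp <- render_pattern_plot(pd, "right", seed = 4)
  parsed <- parse_pattern_plot(rp$image, "24-2", "right")
  d <- attr(parsed, "diagnostics")
  expect_s3_class(d$geometry, "plot_geometry")
  expect_equal(nrow(d$samples), 54L)
  expect_true(all(d$samples$ink_fraction >= 0 & d$samples$ink_fraction <= 1))
  expect_type(d$warnings, "character")
  counts <- count_depressed(parsed, "p5")
  expect_equal(counts, list(count = 8L, total = 54L))
})

test_that("colour and file-format round trips preserve the parse", {
  pd <- random_pd("24-2")
  rp <- render_pattern_plot(pd, "right", seed = 9)
  # colour version: ink rendered in blue on a warm background
  rgb <- array(1, dim = c(dim(rp$image), 3))
  rgb[, , 1] <- ifelse(rp$image < 0.5, 0.1, 1)
  rgb[, , 2] <- ifelse(rp$image < 0.5, 0.2, 0.95)
  rgb[, , 3] <- ifelse(rp$image < 0.5, 0.6, 0.9)
  parsed <- parse_pattern_plot(rgb, "24-2", "right")
  expect_identical(as.character(parsed$category), as.character(pd$category))

  tmp <- withr::local_tempfile(fileext = ".png")
  write_plot_image(rp$image, tmp)
  parsed2 <- parse_pattern_plot(tmp, "24-2", "right")
  expect_identical(as.character(parsed2$category), as.character(pd$category))
  tmp3 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(rp$image, tmp3)
  parsed3 <- parse_pattern_plot(tmp3, "24-2", "right")
  expect_identical(as.character(parsed3$category), as.character(pd$category))
})
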