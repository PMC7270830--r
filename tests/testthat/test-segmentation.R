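test_that("blocks, rows and boxes match the layout on a noiseless render", {
  fx <- tiny_fix()
  lay <- fx$layout
  expect_equal(nrow(fx$blocks$bands), lay$n_blocks)
  expect_equal(sapply(fx$rows, nrow),
               rep(lay$n_entries * lay$rows_per_plot, lay$n_blocks))
  expect_equal(nrow(fx$boxes0), lay$n_blocks * lay$n_entries * lay$rows_per_plot)
  # initial boxes have positive area and are pairwise disjoint per block
  a <- (fx$boxes0$x1 - fx$boxes0$x0) * (fx$boxes0$y1 - fx$boxes0$y0)
  expect_true(all(a > 0))
  for (b in unique(fx$boxes0$block)) {
    bb <- fx$boxes0[fx$boxes0$block == b, ]
    ov <- outer(bb$x0, bb$x1, `<`) & outer(bb$x1, bb$x0, `>`)
    diag(ov) <- FALSE
    expect_false(any(ov & outer(bb$y0, bb$y1, `<`) & outer(bb$y1, bb$y0, `>`)))
  }
})

test_that("initial boxes under-estimate and growing recovers every plant", {
  fx <- tiny_fix()
  # under-estimate: initial vertical extent smaller than grown extent
  expect_true(all(fx$boxes$y1 - fx$boxes$y0 >
                  fx$boxes0$y1 - fx$boxes0$y0))
  # every true plant centre lies inside exactly one grown box
  px <- fx$truth_px
  hits <- integer(nrow(px))
  for (i in seq_len(nrow(fx$boxes))) {
    inside <- px$col >= fx$boxes$x0[i] & px$col < fx$boxes$x1[i] &
      px$row >= fx$boxes$y0[i] & px$row < fx$boxes$y1[i]
    hits <- hits + inside
  }
  expect_true(all(hits == 1))
  # grown boxes in vertically adjacent blocks never overlap
  for (w in unique(fx$boxes$row_in_block)) {
    bb <- fx$boxes[fx$boxes$row_in_block == w, ]
    bb <- bb[order(bb$block), ]
    expect_true(all(diff(as.matrix(bb[, c("y0", "y1")])[, 1]) > 0))
    expect_true(all(bb$y1[-nrow(bb)] <= bb$y0[-1]))
  }
})

test_that("a soil-only band yields no rows, with a warning", {
  soil <- matrix(0.1, 120, 80)
  p <- seg_params(expected_row_length = 40, expected_plant_width = 8)
  band <- tibble::tibble(y0 = 10L, y1 = 60L)
  expect_warning(r <- detect_rows(soil, band, p), "soil-only|no plant rows")
  expect_equal(nrow(r), 0)
})

test_that("an image with no troughs returns a single block with a warning", {
  p <- seg_params(expected_row_length = 20, expected_plant_width = 6,
                  expected_blocks = 3, min_band_frac = 0)
  img <- matrix(1, 60, 40)
  w <- testthat::capture_warnings(bl <- detect_blocks(img, p))
  expect_match(w, "single block", all = FALSE)
  expect_match(w, "expected", all = FALSE)
  expect_equal(nrow(bl$bands), 1)
})

test_that("consensus selection minimises area variance with earliest-tie rule", {
  mkset <- function(widths) tibble::tibble(x0 = 0L, x1 = as.integer(widths),
                                           y0 = 0L, y1 = 1L)
  s1 <- mkset(c(10, 14, 18))   # variance 16
  s2 <- mkset(c(12, 14, 16))   # variance 4
  s3 <- mkset(c(11, 14, 17))   # variance 9
  out <- select_consensus(list(a = s1, b = s2, c = s3))
  expect_equal(out$label, "b")
  expect_equal(out$report$area_variance, c(16, 4, 9))
  # single candidate returns itself
  expect_equal(select_consensus(list(only = s1))$label, "only")
  # exact tie goes to the earlier time point
  out2 <- select_consensus(list(t1 = s2, t2 = mkset(c(16, 14, 12))))
  expect_equal(out2$label, "t1")
  expect_error(select_consensus(list()), "no candidate")
})
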