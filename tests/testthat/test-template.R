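test_that("the template is the sample mean with its reported correlation", {
  w <- matrix(runif(64), 8, 8)
  m <- build_template(windows = list(w, w))
  expect_equal(m$template, w)
  expect_equal(m$correlation, 1)
  # antisymmetric noise cancels in the mean
  noise <- matrix(rnorm(64), 8, 8)
  m2 <- build_template(windows = list(w + noise, w - noise))
  expect_equal(m2$template, w)
  expect_error(build_template(windows = list(w, matrix(0, 4, 4))),
               "inconsistent")
  expect_error(build_template(windows = list(w)), ">= 2")
})

test_that("sample correlation on synthetic plant windows lies in (0, 1]", {
  fx <- tiny_fix()
  expect_gt(fx$template0$correlation, 0)
  expect_lte(fx$template0$correlation, 1)
  # independent check: mean Pearson correlation computed directly
  sam <- pick_template_samples(fx$ndvi, fx$boxes)
  hc <- (28 - 1) %/% 2
  wins <- lapply(seq_len(nrow(sam)), function(i) {
    fx$ndvi[(sam$row[i] - hc + 1):(sam$row[i] - hc + 28),
            (sam$col[i] - hc + 1):(sam$col[i] - hc + 28)]
  })
  tmpl <- Reduce(`+`, wins) / length(wins)
  want <- mean(vapply(wins, function(w) cor(c(tmpl), c(w)), numeric(1)))
  expect_equal(fx$template0$correlation, want, tolerance = 1e-12)
})

test_that("matching a blank image yields no detections", {
  m <- build_template(windows = list(matrix(runif(400), 20, 20),
                                     matrix(runif(400), 20, 20)),
                      width = 20, height = 20, context = 0)
  expect_equal(nrow(match_template(matrix(0.5, 80, 80), m)), 0)
})

test_that("a pasted template is recovered at its location with score 1", {
  set.seed(12)
  tmpl <- matrix(runif(400), 20, 20)
  img <- matrix(0.5, 100, 100)
  img[41:60, 31:50] <- tmpl
  m <- build_template(windows = list(tmpl, tmpl), width = 20, height = 20,
                      context = 0)
  det <- match_template(img, m)
  expect_equal(nrow(det), 1)
  expect_equal(det$col, 30 + (20 - 1) %/% 2)
  expect_equal(det$row, 40 + (20 - 1) %/% 2)
  expect_equal(det$score, 1, tolerance = 1e-8)
})

test_that("a region smaller than the window errors", {
  m <- build_template(windows = list(matrix(1:9 / 9, 3, 3) * 0 + runif(9),
                                     matrix(runif(9), 3, 3)),
                      width = 3, height = 3, context = 0)
  expect_error(match_template(matrix(0, 2, 2), m), "smaller")
})

test_that("noiseless detection has perfect recall and no false positives", {
  fx <- tiny_fix()
  px <- fx$truth_px
  expect_equal(nrow(fx$kept), nrow(px))
  d2 <- vapply(seq_len(nrow(px)), function(i) {
    min((fx$kept$col - px$col[i])^2 + (fx$kept$row - px$row[i])^2)
  }, numeric(1))
  expect_true(all(d2 <= 9))   # every plant matched within 3 px
})

test_that("detection is deterministic", {
  fx <- tiny_fix()
  again <- match_template(fx$ndvi, fx$template)
  expect_identical(fx$cands, again)
})

test_that("template refinement keeps parameters and uses all in-bounds centres", {
  fx <- tiny_fix()
  ref <- refine_template(fx$ndvi, fx$template, fx$kept)
  expect_s3_class(ref, "plant_template")
  expect_equal(dim(ref$template), dim(fx$template$template))
  expect_equal(ref$threshold, fx$template$threshold)
  expect_gt(ref$correlation, 0.8)
  expect_equal(ref$n_samples, nrow(fx$kept))
})
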