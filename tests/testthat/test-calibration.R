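test_that("an exact DN-reflectance line is recovered exactly", {
  obs <- tibble::tibble(band = "red", reflectance_pct = c(6, 11, 22, 33),
                        mean_dn = c(60, 110, 220, 330))
  cal <- fit_calibration(obs)
  expect_equal(cal$gain, 0.1, tolerance = 1e-12)
  expect_equal(cal$offset, 0, tolerance = 1e-10)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)
})

test_that("noisy panels match closed-form least squares", {
  dn <- c(62, 108, 224, 328); refl <- c(6, 11, 22, 33)
  obs <- tibble::tibble(band = "nir", reflectance_pct = refl, mean_dn = dn)
  cal <- fit_calibration(obs)
  # independent normal-equation solution
  gain <- sum((dn - mean(dn)) * (refl - mean(refl))) / sum((dn - mean(dn))^2)
  offset <- mean(refl) - gain * mean(dn)
  expect_equal(cal$gain, gain, tolerance = 1e-12)
  expect_equal(cal$offset, offset, tolerance = 1e-12)
})

test_that("a single panel (or identical DN) is a singular fit", {
  expect_error(fit_calibration(tibble::tibble(
    band = "red", reflectance_pct = 22, mean_dn = 220)), "red")
  expect_error(fit_calibration(tibble::tibble(
    band = "red", reflectance_pct = c(6, 33), mean_dn = c(100, 100))),
    "distinct")
})

test_that("calibration application converts, clips and preserves nodata", {
  m <- matrix(c(220, -20, 1200, -9999), 2, 2)
  r <- mb_raster(list(red = m), 0, 0, 1, nodata = -9999)
  cal <- tibble::tibble(band = "red", gain = 0.1, offset = 0)
  out <- apply_calibration(r, cal)
  expect_equal(out$bands$red[1, 1], 0.22)
  expect_equal(out$bands$red[2, 1], 0)      # clipped from below
  expect_equal(out$bands$red[1, 2], 1)      # clipped from above
  expect_equal(out$bands$red[2, 2], -9999)  # nodata untouched
  expect_equal(unname(attr(out, "clipped")["red"]), 2L)
  expect_error(apply_calibration(r, cal, bands = c("red", "nir")), "nir")
})

test_that("NDVI arithmetic, symmetry and degenerate denominator", {
  expect_equal(compute_ndvi(matrix(0.1), matrix(0.3))[1, 1], 0.5)
  expect_equal(compute_ndvi(matrix(0.2), matrix(0.2))[1, 1], 0)
  expect_true(is.na(compute_ndvi(matrix(0), matrix(0))[1, 1]))
  expect_error(compute_ndvi(matrix(0, 2, 2), matrix(0, 3, 3)), "shapes")
})

test_that("noiseless panel DN invert exactly through the configured gain", {
  fx <- tiny_fix()
  obs <- panel_observations(fx$render$raster, fx$render$panels)
  # render used gain 0.1, offset 0 -> DN = 10 x reflectance_pct
  expect_equal(obs$mean_dn, 10 * obs$reflectance_pct, tolerance = 1e-9)
})

test_that("calibrated NDVI reproduces the rendered ground truth", {
  fx <- tiny_fix()
  nd_truth <- fx$render$ndvi_truth$bands$ndvi
  refl <- apply_calibration(fx$render$raster, fx$calib)
  nd <- compute_ndvi(raster_band(refl, "red"), raster_band(refl, "nir"))
  err <- abs(nd - nd_truth)
  expect_lt(max(err, na.rm = TRUE), 1e-6)
  expect_true(all(abs(nd) <= 1 + 1e-12, na.rm = TRUE))
})
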