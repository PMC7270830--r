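test_that("raster write/read round-trips values, geotransform, crs, nodata", {
  set.seed(1)
  vals <- matrix(round(runif(100, -50, 400), 2), 10, 10)
  # store at float32 precision so the round-trip is bit-exact
  vals <- matrix(readBin(writeBin(as.numeric(vals), raw(), size = 4),
                         "numeric", 100, size = 4), 10, 10)
  r <- mb_raster(list(red = vals, nir = vals * 2), x0 = 594000.25,
                 y0 = 5810000.5, gsd = 0.02, crs = "EPSG:32754",
                 nodata = -9999)
  f <- file.path(withr::local_tempdir(), "r1")
  write_raster(r, f)
  r2 <- read_raster(f)
  expect_identical(r2$bands$red, r$bands$red)
  expect_identical(r2$bands$nir, r$bands$nir)
  expect_identical(r2$x0, r$x0)
  expect_identical(r2$y0, r$y0)
  expect_identical(r2$gsd, r$gsd)
  expect_identical(r2$crs, r$crs)
  expect_identical(r2$nodata, r$nodata)
})

test_that("missing header or data file raises a format/io error", {
  d <- withr::local_tempdir()
  r <- mb_raster(list(a = matrix(0, 2, 2)), 0, 0, 1)
  write_raster(r, file.path(d, "x"))
  file.remove(file.path(d, "x.hdr.json"))
  expect_error(read_raster(file.path(d, "x")), "header")
  expect_error(read_raster(file.path(d, "nope")), "not found")
})

test_that("header missing the geotransform is rejected by name", {
  d <- withr::local_tempdir()
  r <- mb_raster(list(a = matrix(0, 2, 2)), 0, 0, 1)
  write_raster(r, file.path(d, "x"))
  hdr <- jsonlite::read_json(file.path(d, "x.hdr.json"),
                             simplifyVector = TRUE)
  hdr$crs <- NULL
  jsonlite::write_json(hdr, file.path(d, "x.hdr.json"), auto_unbox = TRUE)
  expect_error(read_raster(file.path(d, "x")), "crs")
})

test_that("pixel/world transforms are exact and invertible", {
  r <- mb_raster(list(a = matrix(0, 50, 50)), x0 = 1000, y0 = 2000,
                 gsd = 0.02)
  # origin pixel corner = geotransform translation terms
  w <- pixel_to_world(r, 0, 0)
  expect_equal(w$x, 1000)
  expect_equal(w$y, 2000)
  # 100 pixels at 2 cm = 2.0 m
  expect_equal(pixel_to_world(r, 100, 0)$x - pixel_to_world(r, 0, 0)$x, 2.0)
  # round trip
  set.seed(2)
  cols <- runif(20, 0, 50); rows <- runif(20, 0, 50)
  w <- pixel_to_world(r, cols, rows, offset = 0.5)
  p <- world_to_pixel(r, w$x, w$y, offset = 0.5)
  expect_true(all(abs(p$col - cols) < 1e-9))
  expect_true(all(abs(p$row - rows) < 1e-9))
})

test_that("a five-band render carries the band labels in wavelength order", {
  lay <- trial_layout(n_entries = 1, n_reps = 1, rng_seed = 2)
  ro <- render_ortho(generate_layout(lay),
                     bands = c("blue", "green", "red", "rededge", "nir"))
  expect_identical(names(ro$raster$bands),
                   c("blue", "green", "red", "rededge", "nir"))
  expect_true(all(diff(ro$raster$wavelengths) > 0))
})
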