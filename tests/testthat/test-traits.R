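test_that("zonal NDVI statistics aggregate the covered pixels", {
  m <- matrix(0.5, 10, 10)
  polys <- tibble::tibble(plant_id = "p1", x0 = 2L, x1 = 6L, y0 = 1L,
                          y1 = 5L)
  st <- extract_ndvi_stats(m, polys)
  expect_equal(st$ndvi_mean, 0.5)
  expect_equal(st$n_ndvi_pixels, 16L)
  # explicit four-pixel polygon
  m2 <- matrix(0, 2, 2); m2[] <- c(0.2, 0.4, 0.6, 0.8)
  st2 <- extract_ndvi_stats(m2, tibble::tibble(plant_id = "q", x0 = 0L,
                                               x1 = 2L, y0 = 0L, y1 = 2L))
  expect_equal(st2$ndvi_mean, 0.5)
  expect_equal(st2$ndvi_median, 0.5)
  expect_equal(st2$ndvi_max, 0.8)
  expect_error(extract_ndvi_stats(m, tibble::tibble(plant_id = "r",
                                                    x0 = 5L, x1 = 20L,
                                                    y0 = 0L, y1 = 2L)),
               "outside")
})

test_that("zonal statistics match a brute-force per-pixel loop", {
  set.seed(9)
  m <- matrix(runif(80 * 90, -0.2, 0.9), 80, 90)
  m[sample(length(m), 200)] <- NA
  polys <- tibble::tibble(
    plant_id = sprintf("p%02d", 1:20),
    x0 = sample(0:70, 20), y0 = sample(0:60, 20)
  )
  polys$x1 <- polys$x0 + sample(1:19, 20, replace = TRUE)
  polys$y1 <- polys$y0 + sample(1:19, 20, replace = TRUE)
  st <- suppressMessages(extract_ndvi_stats(m, polys))
  for (i in seq_len(nrow(polys))) {
    acc <- c()
    for (cc in polys$x0[i]:(polys$x1[i] - 1L)) {
      for (rr in polys$y0[i]:(polys$y1[i] - 1L)) {
        v <- m[rr + 1L, cc + 1L]
        if (!is.na(v)) acc <- c(acc, v)
      }
    }
    expect_equal(st$n_ndvi_pixels[i], length(acc))
    if (length(acc)) {
      expect_equal(st$ndvi_mean[i], mean(acc))
      expect_equal(st$ndvi_median[i], median(acc))
      expect_equal(st$ndvi_max[i], max(acc))
    }
  }
})

test_that("polygons with no valid pixels are flagged", {
  m <- matrix(NA_real_, 6, 6)
  m[1, 1] <- 0.5
  st <- suppressMessages(extract_ndvi_stats(
    m, tibble::tibble(plant_id = "e", x0 = 2L, x1 = 5L, y0 = 2L, y1 = 5L)))
  expect_true(st$flag_no_pixels)
  expect_equal(st$n_ndvi_pixels, 0L)
  expect_true(is.na(st$ndvi_mean))
})

test_that("every plant's polygon NDVI mean exceeds the soil background", {
  fx <- tiny_fix()
  st <- fx$traits
  expect_true(all(st$ndvi_mean > fx$render$soil_ndvi))
})

test_that("the combined predictor follows its definition", {
  expect_equal(compute_predictor(0, 25)[1], 0)
  expect_equal(compute_predictor(1, 10)[1], 10)
  expect_equal(compute_predictor(0.8, 20)[1], 12.8)
  expect_true(is.na(compute_predictor(NA, 10)[1]))
  expect_match(attr(compute_predictor(0.5, 1), "predictor_definition"),
               "ndvi\\^2")
  # configurable exponent is recorded
  expect_equal(compute_predictor(0.5, 8, exponent = 1)[1], 4)
})

test_that("trait records flag missing heights and skip their predictor", {
  st <- tibble::tibble(plant_id = c("a", "b"), ndvi_mean = c(0.5, 0.6),
                       ndvi_median = c(0.5, 0.6), ndvi_max = c(0.7, 0.8),
                       n_ndvi_pixels = c(10L, 12L),
                       flag_no_pixels = c(FALSE, FALSE))
  h <- tibble::tibble(plant_id = "a", height_cm = 12, n_height_samples = 3L)
  tr <- build_trait_records(st, h)
  expect_equal(tr$flag, c("ok", "no-height"))
  expect_true(is.na(tr$ndvisq_ph[2]))
  expect_equal(tr$ndvisq_ph[1], 0.25 * 12)
})
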