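test_that("seasonal equations evaluate to their published coefficients", {
  for (mode in c("reconstructed", "as_printed")) {
    m <- season_model(mode)
    expect_equal(predict_dmy(0, "winter2018", m), -4.62)
    expect_equal(predict_dmy(0, "late-spring2018_2", m), -4.62 + 16.86)
  }
  # slope arithmetic on the late-spring equations (identical in both modes)
  expect_equal(predict_dmy(1, "late-spring2018_1", season_model()),
               -4.62 + 5.088 + 5.76 + 1.49)
  # winter slope differs between modes away from predictor 0
  expect_equal(predict_dmy(2, "winter2018", season_model("reconstructed")),
               -4.62 + 2 * 5.088)
  expect_equal(predict_dmy(2, "winter2018", season_model("as_printed")),
               -4.62 + 2)
  expect_error(predict_dmy(1, "summer2019"), "valid seasons")
})

test_that("season differences at fixed predictor equal the printed offsets", {
  m <- season_model()
  p <- 3.7
  expect_equal(predict_dmy(p, "late-spring2018_1", m) -
                 predict_dmy(p, "winter2018", m), 5.76 + 1.49 * p)
  expect_equal(predict_dmy(p, "late-spring2018_2", m) -
                 predict_dmy(p, "winter2018", m), 16.86 + 3.68 * p)
})

test_that("noiseless parameter recovery is exact to 1e-8", {
  set.seed(6)
  d <- tidyr::expand_grid(season = dmy_seasons,
                          ndvisq_ph = runif(200, 0, 8)) |>
    dplyr::mutate(measured_g = predict_dmy(ndvisq_ph, season))
  fit <- fit_seasonal_model(d)
  truth <- season_model()
  expect_lt(abs(fit$model$base_intercept - truth$base_intercept), 1e-8)
  expect_lt(abs(fit$model$base_slope - truth$base_slope), 1e-8)
  for (s in dmy_seasons[-1]) {
    expect_lt(abs(fit$model$int_offset[[s]] - truth$int_offset[[s]]), 1e-8)
    expect_lt(abs(fit$model$slope_offset[[s]] - truth$slope_offset[[s]]), 1e-8)
  }
})

test_that("degenerate designs are rejected with informative errors", {
  d1 <- tibble::tibble(ndvisq_ph = runif(10), season = "winter2018",
                       measured_g = runif(10))
  expect_error(fit_seasonal_model(d1), ">= 2 seasons")
  d2 <- tibble::tibble(ndvisq_ph = 1,
                       season = rep(dmy_seasons[1:2], each = 5),
                       measured_g = runif(10))
  expect_error(fit_seasonal_model(d2), "variance")
  d3 <- tibble::tibble(ndvisq_ph = runif(4),
                       season = c("winter2018", "winter2018",
                                  "late-spring2018_1", "late-spring2018_1"),
                       measured_g = runif(4))
  expect_error(fit_seasonal_model(d3), ">= 3 observations")
})

test_that("tidy and glance expose the interaction fit", {
  set.seed(8)
  d <- tidyr::expand_grid(season = dmy_seasons,
                          ndvisq_ph = runif(50, 0, 6)) |>
    dplyr::mutate(measured_g = predict_dmy(ndvisq_ph, season) + rnorm(150))
  fit <- fit_seasonal_model(d)
  td <- tidy(fit)
  expect_equal(nrow(td), 6)
  expect_true(all(c("term", "estimate", "std.error") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$nobs, 150)
  expect_equal(gl$n_seasons, 3)
})

test_that("plot aggregation conserves mass and flags missing plants", {
  pp <- tibble::tibble(plant_id = sprintf("p%03d", 1:96),
                       plot_id = "B01-P01", predicted_g = 10)
  agg <- aggregate_plot(pp)
  expect_equal(agg$predicted_kg, 0.96)
  expect_equal(agg$n_summed, 96L)
  pp$predicted_g[1] <- NA
  agg2 <- aggregate_plot(pp)
  expect_equal(agg2$n_summed, 95L)
  expect_true(agg2$flag_incomplete)
  expect_equal(agg2$predicted_kg * 1000,
               sum(pp$predicted_g, na.rm = TRUE))
  expect_error(aggregate_plot(pp, plots = tibble::tibble(plot_id = "X")),
               "unknown plot")
})

test_that("simulated harvests follow the seasonal equation exactly at zero noise", {
  lay <- trial_layout(n_entries = 2, n_reps = 2, rng_seed = 14)
  tr <- generate_layout(lay)
  h <- simulate_harvest(tr, "winter2018", noise_sd = 0)
  want <- predict_dmy(tr$plants$true_ndvi^2 * tr$plants$true_height,
                      "winter2018")
  expect_equal(h$plants$measured_g, want)
  # plot kg are plant gram sums / 1000
  s <- tapply(h$plants$measured_g, h$plants$plot_id, sum) / 1000
  expect_equal(as.numeric(s[h$plots$plot_id]), h$plots$measured_kg)
  expect_error(simulate_harvest(tr, "autumn2018"), "valid seasons")
})

test_that("validation metrics match hand regression", {
  d0 <- tibble::tibble(predicted_kg = c(1, 2, 3), measured_kg = c(1, 2, 3))
  v0 <- validate_predictions(d0)
  expect_equal(v0$slope, 1)
  expect_equal(v0$r_squared, 1)
  expect_equal(v0$rmse_raw, 0)
  d1 <- tibble::tibble(predicted_kg = c(1, 2, 3), measured_kg = c(2, 3, 4))
  v1 <- validate_predictions(d1)
  expect_equal(v1$slope, 1)
  expect_equal(v1$r_squared, 1)
  expect_equal(v1$rmse_raw, 1)      # constant offset of one unit
  expect_equal(v1$rmse_resid, 0)
  # anti-correlated pairs: R2 is sign-blind, the slope is not
  d2 <- tibble::tibble(predicted_kg = c(1, 2, 3), measured_kg = c(4, 3, 2))
  v2 <- validate_predictions(d2)
  expect_equal(v2$r_squared, 1)
  expect_lt(v2$slope, 0)
  expect_error(validate_predictions(
    tibble::tibble(predicted_kg = c(1, 1, 1), measured_kg = 1:3)),
    "zero variance")
  expect_error(validate_predictions(d2[1:2, ]), ">= 3")
  # tidy/autoplot accessors
  expect_equal(nrow(tidy(v2)), 1)
  expect_s3_class(autoplot(v1), "ggplot")
})
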