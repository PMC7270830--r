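test_that("ultrasonic ranges follow mount height minus plant height", {
  lay <- trial_layout(n_entries = 1, n_reps = 1, rng_seed = 21)
  tr <- generate_layout(lay)
  # force known heights for exact range checks
  tr$plants$true_height[] <- 15
  track <- simulate_height_track(tr)
  # sensor 3 (offset 0) drives along each row centre: over plants range
  # is 0.6 - 0.15 = 0.45, over bare ground exactly 0.6
  s3 <- track$range_m[track$sensor_index == 3]
  expect_setequal(round(unique(s3), 10), c(0.45, 0.6))
  # an off-row sensor (offset 0.3, between rows) only sees bare ground
  s4 <- track$range_m[track$sensor_index == 4 ]
  expect_true(all(s4 == 0.6 | s4 == 0.45))
})

test_that("tracks are identical on re-simulation with a fixed seed", {
  lay <- trial_layout(n_entries = 1, n_reps = 1, rng_seed = 33)
  tr <- generate_layout(lay)
  t1 <- simulate_height_track(tr, rig = sensor_rig(range_noise_sd = 0.01))
  t2 <- simulate_height_track(tr, rig = sensor_rig(range_noise_sd = 0.01))
  expect_identical(t1, t2)
})

test_that("an empty row selection warns and returns an empty track", {
  lay <- trial_layout(n_entries = 1, n_reps = 1, rng_seed = 2)
  tr <- generate_layout(lay)
  expect_warning(t0 <- simulate_height_track(tr, rows = "no-such-row"),
                 "no rows")
  expect_equal(nrow(t0), 0)
})

test_that("sensor offsets rotate with the heading (due north -> east)", {
  # two fixes driving due north at the UTM anchor; +1 m offset = right of
  # travel = east of the track
  ll <- utm_to_latlon(c(594000, 594000), c(5809000, 5809010), zone = 54)
  track <- tibble::tibble(timestamp = c("t1", "t2"), lat = ll$lat,
                          lon = ll$lon, sensor_index = 1L,
                          range_m = 0.6)
  rig <- sensor_rig(n_sensors = 1, lateral_offsets = 1, mount_height = 0.6)
  hs <- project_track(track, rig, zone = 54, south = TRUE)
  expect_equal(hs$x, c(594001, 594001), tolerance = 1e-6)
  expect_equal(hs$y, c(5809000, 5809010), tolerance = 1e-6)
})

test_that("stationary fixes carry the last moving heading", {
  ll <- utm_to_latlon(c(594000, 594000, 594000), c(5809000, 5809010, 5809010),
                      zone = 54)
  track <- tibble::tibble(timestamp = c("t1", "t2", "t3"), lat = ll$lat,
                          lon = ll$lon, sensor_index = 1L, range_m = 0.5)
  rig <- sensor_rig(n_sensors = 1, lateral_offsets = 1)
  hs <- project_track(track, rig, zone = 54)
  # the duplicated fix keeps the northward heading: offset still east
  expect_equal(hs$x[3], 594001, tolerance = 1e-6)
  expect_equal(hs$height_cm, rep(10, 3), tolerance = 1e-9)
})

test_that("heights match ground truth and are order/direction invariant", {
  fx <- tiny_fix()
  j <- dplyr::inner_join(fx$heights,
                         fx$truth$plants[, c("plant_id", "true_height")],
                         by = "plant_id")
  expect_equal(nrow(j), nrow(fx$truth$plants))
  expect_lt(max(abs(j$height_cm - j$true_height)), 0.5)
  # shuffling the samples does not change the per-plant medians
  hs <- project_track(fx$track)
  set.seed(1)
  hs2 <- hs[sample(nrow(hs)), ]
  m1 <- suppressMessages(match_heights(hs, fx$polys, fx$rect$raster))
  m2 <- suppressMessages(match_heights(hs2, fx$polys, fx$rect$raster))
  expect_equal(dplyr::arrange(m1, plant_id), dplyr::arrange(m2, plant_id))
})
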