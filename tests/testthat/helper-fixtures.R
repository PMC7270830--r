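# Shared fixtures, built once per test run.
#
# tiny_fix(): a 3-entry x 2-block synthetic trial (576 plants) carried all
# the way through rendering, calibration, rectification, segmentation,
# template matching, polygon splitting, NDVI/height extraction and a
# simulated harvest. Deterministic (fixed seed).

tiny_fix <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    lay <- trial_layout(n_entries = 3, n_reps = 2, rng_seed = 42)
    truth <- generate_layout(lay)
    ro <- render_ortho(truth)
    cal <- fit_calibration(panel_observations(ro$raster, ro$panels))
    refl <- apply_calibration(ro$raster, cal)
    nd_r <- compute_ndvi(refl)
    corners <- ro$gcps[match(c("c-nw", "c-ne", "c-se", "c-sw"), ro$gcps$id), ]
    rect <- perspective_transform(nd_r, corners)
    ndvi <- raster_band(rect$raster, "ndvi")
    params <- seg_params(expected_row_length = lay$plot_length / lay$gsd,
                         expected_plant_width = 12,
                         expected_blocks = lay$n_blocks)
    blocks <- suppressMessages(detect_blocks(ndvi, params))
    rows <- lapply(seq_len(nrow(blocks$bands)),
                   function(i) detect_rows(ndvi, blocks$bands[i, ], params))
    boxes0 <- initial_row_boxes(blocks, rows)
    boxes <- suppressMessages(link_and_grow(boxes0, ndvi))
    model0 <- build_template(ndvi, pick_template_samples(ndvi, boxes))
    kept0 <- suppressMessages(filter_and_qc(match_template(ndvi, model0),
                                            boxes, image_dim = dim(ndvi)))
    model <- refine_template(ndvi, model0, kept0)
    cands <- match_template(ndvi, model)
    kept <- suppressMessages(filter_and_qc(cands, boxes,
                                           image_dim = dim(ndvi)))
    polys <- suppressMessages(split_row_polygons(boxes, kept,
                                                 rows_per_plot = 3))
    track <- simulate_height_track(truth)
    heights <- suppressMessages(match_heights(project_track(track),
                                              polys, rect$raster))
    stats <- suppressMessages(extract_ndvi_stats(ndvi, polys))
    traits <- build_trait_records(stats, heights)
    harvest <- simulate_harvest(truth, "winter2018", noise_sd = 0)
    # true plant centres in rectified pixel coordinates
    px <- world_to_pixel(rect$raster, truth$plants$x, truth$plants$y)
    cache <<- list(layout = lay, truth = truth, render = ro, calib = cal,
                   rect = rect, ndvi = ndvi, params = params,
                   blocks = blocks, rows = rows, boxes0 = boxes0,
                   boxes = boxes, template0 = model0, template = model,
                   cands = cands,
                   kept = kept, polys = polys, track = track,
                   heights = heights, traits = traits, harvest = harvest,
                   truth_px = tibble::tibble(plant_id = truth$plants$plant_id,
                                             col = floor(px$col),
                                             row = floor(px$row)))
    cache
  }
})

# brute-force 1-D morphology oracle: direct sliding-window min/max with
# +/-Inf border padding (independent of the package implementation)
oracle_erode <- function(x, len) {
  h <- (len - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- max(1L, i - h):min(n, i + h)
    min(x[w])
  }, numeric(1))
}
oracle_dilate <- function(x, len) {
  h <- (len - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- max(1L, i - h):min(n, i + h)
    max(x[w])
  }, numeric(1))
}
oracle_process <- function(x, feature_length) {
  se_odd <- function(L) if (L %% 2 == 0) L + 1L else L
  se1 <- se_odd(max(1L, feature_length %/% 2L))
  se2 <- se_odd(max(1L, feature_length %/% 3L))
  oracle_erode(oracle_dilate(oracle_erode(x, se1), se1), se2)
}
# brute-force regional minima by scanning runs
oracle_minima <- function(x) {
  n <- length(x)
  res <- NULL
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && x[j + 1L] == x[i]) j <- j + 1L
    lv <- if (i == 1L) Inf else x[i - 1L]
    rv <- if (j == n) Inf else x[j + 1L]
    # a run spanning the whole profile is not a trough
    if (x[i] < lv && x[i] < rv && !(i == 1L && j == n)) {
      res <- rbind(res, c(left = i, right = j, center = (i + j) %/% 2L,
                          value = x[i]))
    }
    i <- j + 1L
  }
  if (is.null(res)) {
    tibble::tibble(left = integer(), right = integer(), center = integer(),
                   value = numeric())
  } else {
    tibble::as_tibble(as.data.frame(res))
  }
}
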