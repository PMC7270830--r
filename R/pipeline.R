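# End-to-end orchestration: simulate writes a full synthetic dataset to
# disk; run_pipeline executes calibrate -> NDVI -> rectify -> blocks/rows ->
# box growing -> consensus -> centres -> plant polygons -> NDVI stats ->
# heights -> predict -> aggregate -> validate, with a run manifest.

#' Write a complete synthetic trial dataset to a directory
#'
#' @param layout a [trial_layout()].
#' @param dir output directory (created if needed).
#' @param bands bands to render.
#' @param noise_sd DN noise passed to [render_ortho()].
#' @param season harvest season for the simulated destructive harvest.
#' @param harvest_noise_sd per-plant harvest noise, grams.
#' @param write_track simulate and write the ultrasonic height track.
#' @param rig the [sensor_rig()] for the track.
#' @return invisible list of file paths and in-memory objects.
#' @export
simulate_trial <- function(layout = trial_layout(), dir,
                           bands = c("red", "nir"), noise_sd = 0,
                           season = "winter2018", harvest_noise_sd = 0,
                           write_track = TRUE, rig = sensor_rig()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(dir, ...)
  truth <- generate_layout(layout)
  ro <- render_ortho(truth, bands = bands, noise_sd = noise_sd)
  write_raster(ro$raster, pth("ortho"))
  write_raster(ro$ndvi_truth, pth("ndvi_truth"))
  write.csv(truth$plants, pth("plants.csv"), row.names = FALSE)
  write.csv(truth$rows, pth("rows.csv"), row.names = FALSE)
  write.csv(truth$plots, pth("plots.csv"), row.names = FALSE)
  write.csv(ro$gcps, pth("gcps.csv"), row.names = FALSE)
  write.csv(ro$panels, pth("panels.csv"), row.names = FALSE)
  harvest <- simulate_harvest(truth, season, noise_sd = harvest_noise_sd)
  write.csv(harvest$plants, pth("harvest_plants.csv"), row.names = FALSE)
  write.csv(harvest$plots, pth("harvest_plots.csv"), row.names = FALSE)
  track_path <- NULL
  if (write_track) {
    track <- simulate_height_track(truth, rig)
    track_path <- pth("track.csv")
    write.csv(track, track_path, row.names = FALSE)
  }
  yaml::write_yaml(list(
    n_entries = layout$n_entries, n_reps = layout$n_reps,
    rows_per_plot = layout$rows_per_plot,
    plants_per_row = layout$plants_per_row,
    plant_spacing = layout$plant_spacing, row_spacing = layout$row_spacing,
    plot_length = layout$plot_length, plot_width = layout$plot_width,
    gsd = layout$gsd, alley_width = layout$alley_width,
    rng_seed = layout$rng_seed, season = season
  ), pth("layout.yaml"))
  invisible(list(dir = dir, truth = truth, render = ro,
                 harvest = harvest, track = track_path))
}

#' Default pipeline configuration for a dataset directory
#'
#' @param dir dataset directory written by [simulate_trial()].
#' @param layout the [trial_layout()] used (supplies the segmentation
#'   parameters: expected row length and plant width in pixels).
#' @param ... overrides merged into the config list.
#' @return named config list for [run_pipeline()].
#' @export
pipeline_config <- function(dir, layout, ...) {
  cfg <- list(
    raster = file.path(dir, "ortho"),
    gcps = file.path(dir, "gcps.csv"),
    panels = file.path(dir, "panels.csv"),
    track = if (file.exists(file.path(dir, "track.csv")))
      file.path(dir, "track.csv") else NULL,
    edits = NULL,
    measured_plots = file.path(dir, "harvest_plots.csv"),
    out_dir = file.path(dir, "out"),
    season = "winter2018",
    model_mode = "reconstructed",
    corner_ids = c("c-nw", "c-ne", "c-se", "c-sw"),
    expected_row_length_px = round(layout$plot_length / layout$gsd),
    expected_plant_width_px = max(6, round(0.24 / layout$gsd)),
    expected_blocks = layout$n_blocks,
    rows_per_plot = layout$rows_per_plot,
    background_t = NULL,
    grow_variant = "prose",
    template = list(width = 20, height = 20, context = 4,
                    threshold = 0.6, tolerance = 3, n_samples = 35,
                    refine = TRUE),
    samples = NULL,
    mount_height = 0.6,
    seed = layout$rng_seed
  )
  utils::modifyList(cfg, list(...))
}

#' Run the full phenotyping pipeline
#'
#' Executes the stages in workflow order on a dataset described by a config
#' list (or YAML path): empirical-line calibration, NDVI, perspective
#' rectification on the corner GCPs, block/row segmentation with box
#' growing, consensus selection, template matching, plant-polygon
#' construction, per-plant NDVI statistics, height extraction (when a track
#' is configured), seasonal DMY prediction, plot aggregation and validation
#' against measured plot harvests (when available). Writes CSV/GeoJSON
#' artifacts plus a JSON manifest to `config$out_dir`.
#'
#' @param config named list (see [pipeline_config()]) or YAML file path.
#' @param quiet suppress progress messages.
#' @return invisible list of results (`traits`, `predictions`,
#'   `plot_predictions`, `polygons`, `boxes`, `validation`, `manifest`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("phenorow")),
                   r_version = R.version.string,
                   seed = config$seed,
                   config_hash = rlang::hash(config),
                   stages = list(), counts = list())
  done_paths <- character()
  t_all <- Sys.time()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s [completed artifacts: %s]",
                   name, conditionMessage(e),
                   if (length(done_paths)) paste(done_paths, collapse = ", ")
                   else "none"), call. = FALSE)
    })
    el <- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
    manifest$stages[[name]] <<- el
    if (!quiet) message(sprintf("[%s] done in %.2fs", name, el))
    res
  }

  raster <- stage("read_raster", read_raster(config$raster))
  panels <- stage("read_panels", tibble::as_tibble(
    read.csv(config$panels, stringsAsFactors = FALSE)))
  calib <- stage("calibrate", {
    obs <- panel_observations(raster, panels)
    fit_calibration(obs)
  })
  ndvi_r <- stage("ndvi", {
    refl <- apply_calibration(raster, calib, bands = c("red", "nir"))
    nd <- compute_ndvi(refl)
    attr(nd, "clipped") <- sum(attr(refl, "clipped"))
    nd
  })
  manifest$counts$clipped_pixels <- attr(ndvi_r, "clipped")
  rect <- stage("rectify", {
    gcps <- read.csv(config$gcps, stringsAsFactors = FALSE)
    corners <- gcps[match(config$corner_ids, gcps$id), ]
    perspective_transform(ndvi_r, corners)
  })
  ndvi <- raster_band(rect$raster, "ndvi")

  params <- seg_params(
    expected_row_length = config$expected_row_length_px,
    expected_plant_width = config$expected_plant_width_px,
    background_t = config$background_t,
    expected_blocks = config$expected_blocks
  )
  blocks <- stage("detect_blocks", detect_blocks(ndvi, params))
  manifest$counts$blocks <- nrow(blocks$bands)
  rows_by_block <- stage("detect_rows", purrr::map(
    seq_len(nrow(blocks$bands)),
    function(i) detect_rows(ndvi, blocks$bands[i, ], params)))
  boxes0 <- stage("initial_boxes", initial_row_boxes(blocks, rows_by_block))
  boxes <- stage("box_growing", link_and_grow(
    boxes0, ndvi, t = config$background_t,
    variant = config$grow_variant %||% "prose"))
  cons <- stage("consensus", select_consensus(
    stats::setNames(list(boxes), config$time_point %||% "t01")))
  boxes <- cons$chosen
  manifest$counts$row_polygons <- nrow(boxes)

  tp <- config$template
  model <- stage("build_template", {
    samples <- if (!is.null(config$samples)) {
      tibble::as_tibble(read.csv(config$samples, stringsAsFactors = FALSE))
    } else {
      pick_template_samples(ndvi, boxes, n = tp$n_samples %||% 35,
                            window_half = (tp$width + 2 * tp$context) %/% 2)
    }
    build_template(ndvi, samples, width = tp$width, height = tp$height,
                   context = tp$context, threshold = tp$threshold,
                   tolerance = tp$tolerance)
  })
  centers <- stage("match_template", match_template(ndvi, model))
  manifest$counts$candidate_centers <- nrow(centers)
  kept <- stage("filter_qc", filter_and_qc(centers, boxes,
                                           edits = config$edits,
                                           image_dim = dim(ndvi)))
  if (isTRUE(tp$refine %||% TRUE)) {
    # one template-refinement pass: rebuild from the accepted detections
    # (covering the full range of plant sizes) and re-match
    model <- stage("refine_template", refine_template(ndvi, model, kept))
    centers <- stage("rematch_template", match_template(ndvi, model))
    kept <- stage("refilter_qc", filter_and_qc(centers, boxes,
                                               edits = config$edits,
                                               image_dim = dim(ndvi)))
    manifest$counts$template_correlation <- model$correlation
  }
  manifest$counts$kept_centers <- nrow(kept)
  polys <- stage("plant_polygons", split_row_polygons(
    boxes, kept, rows_per_plot = config$rows_per_plot %||% 3))
  manifest$counts$plant_polygons <- nrow(polys)

  traits <- stage("ndvi_stats", {
    st <- extract_ndvi_stats(ndvi, polys)
    heights <- NULL
    n_hs <- 0L
    if (!is.null(config$track)) {
      rig <- sensor_rig(mount_height = config$mount_height %||% 0.6)
      hs <- project_track(config$track, rig)
      heights <- match_heights(hs, polys, rect$raster)
      n_hs <- nrow(hs)
    }
    tr <- build_trait_records(st, heights)
    attr(tr, "n_height_samples") <- n_hs
    tr
  })
  manifest$counts$height_samples <- attr(traits, "n_height_samples")

  season <- config$season %||% "winter2018"
  model_dmy <- season_model(config$model_mode %||% "reconstructed")
  have_height <- any(!is.na(traits$height_cm))
  predictions <- stage("predict", {
    if (have_height) {
      dplyr::mutate(traits,
                    season = season,
                    predicted_g = predict_dmy(.data$ndvisq_ph, season,
                                              model_dmy),
                    mode = model_dmy$mode)
    } else {
      if (!quiet) message("no height data; DMY prediction skipped (flagged)")
      dplyr::mutate(traits, season = season, predicted_g = NA_real_,
                    mode = "skipped-no-height")
    }
  })

  plot_pred <- stage("aggregate", {
    pp <- dplyr::left_join(predictions,
                           polys[c("plant_id", "plot_id")], by = "plant_id")
    aggregate_plot(pp)
  })

  validation <- NULL
  if (have_height && !is.null(config$measured_plots) &&
      file.exists(config$measured_plots)) {
    validation <- stage("validate", {
      meas <- tibble::as_tibble(
        read.csv(config$measured_plots, stringsAsFactors = FALSE))
      joined <- dplyr::inner_join(plot_pred, meas, by = "plot_id")
      validate_predictions(joined)
    })
  }

  stage("write_outputs", {
    op <- function(f) file.path(out_dir, f)
    write.csv(traits, op("traits.csv"), row.names = FALSE)
    write.csv(predictions, op("predictions.csv"), row.names = FALSE)
    write.csv(plot_pred, op("plot_predictions.csv"), row.names = FALSE)
    write.csv(cons$report, op("variance_report.csv"), row.names = FALSE)
    write_polygons_geojson(boxes, rect$raster, op("row_polygons.geojson"))
    write_polygons_geojson(
      polys[c("plant_id", "plot_id", "position", "x0", "x1", "y0", "y1")],
      rect$raster, op("plant_polygons.geojson"))
    write_points_geojson(kept[c("col", "row", "score", "box_id",
                                "provenance")],
                         rect$raster, op("centers.geojson"))
    if (!is.null(validation)) {
      jsonlite::write_json(validation[c("n", "slope", "intercept",
                                        "r_squared", "rmse_raw",
                                        "rmse_resid")],
                           op("validation.json"), auto_unbox = TRUE,
                           digits = NA)
    }
    TRUE
  })

  manifest$counts$plants_with_height <- sum(!is.na(traits$height_cm))
  manifest$total_seconds <- round(as.numeric(
    difftime(Sys.time(), t_all, units = "secs")), 2)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(traits = traits, predictions = predictions,
                 plot_predictions = plot_pred, polygons = polys,
                 boxes = boxes, centers = kept, validation = validation,
                 calibration = calib, manifest = manifest))
}
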