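# Ground-vehicle ultrasonic height rig: track simulation, projection of
# RTK fixes to the field CRS with per-sensor lateral offsets, and matching
# of height samples to plant polygons.

#' Ultrasonic sensor rig description
#'
#' @param n_sensors number of ultrasonic sensors on the boom.
#' @param lateral_offsets metres from the RTK antenna, positive to the
#'   right of travel; must be distinct, one per sensor.
#' @param mount_height boom height above ground, metres (> 0).
#' @param sample_rate samples per second per sensor.
#' @param range_noise_sd Gaussian range noise, metres.
#' @return list of class `sensor_rig`.
#' @export
sensor_rig <- function(n_sensors = 6,
                       lateral_offsets = c(-0.6, -0.3, 0, 0.3, 0.6, 0.9),
                       mount_height = 0.6, sample_rate = 10,
                       range_noise_sd = 0) {
  if (mount_height <= 0) stop("mount_height must be > 0", call. = FALSE)
  if (length(lateral_offsets) != n_sensors ||
      anyDuplicated(lateral_offsets)) {
    stop("lateral_offsets must be distinct, one per sensor", call. = FALSE)
  }
  structure(list(n_sensors = n_sensors, lateral_offsets = lateral_offsets,
                 mount_height = mount_height, sample_rate = sample_rate,
                 range_noise_sd = range_noise_sd),
            class = "sensor_rig")
}

# nearest plant under a sensor position; returns its height (cm) or NA
.plant_under <- function(truth, x, y) {
  l <- truth$layout
  rows <- truth$rows
  centers <- sort(unique(rows$center_x))
  mids <- (centers[-1] + centers[-length(centers)]) / 2
  ci <- findInterval(x, mids) + 1L
  cx <- centers[ci]
  period <- l$plot_length + l$alley_width
  block <- floor((l$origin_y - y) / period) + 1
  wy1 <- l$origin_y - (block - 1) * period
  pos <- round((wy1 - y - l$plant_spacing / 2) / l$plant_spacing) + 1
  key <- paste(round(cx * 1000), block, pos)
  pk <- paste(round(truth$plants$x * 1000), truth$plants$block,
              truth$plants$position)
  m <- match(key, pk)
  px <- truth$plants$x[m]; py <- truth$plants$y[m]
  r <- truth$plants$radius[m]
  hit <- !is.na(m) & (x - px)^2 + (y - py)^2 <= r^2
  ifelse(hit, truth$plants$true_height[m], NA_real_)
}

#' Simulate an ultrasonic height track over the trial
#'
#' The vehicle makes one straight pass along each plant row at constant
#' speed (with a short bare-ground lead-in/out); at each fix every sensor
#' records its ultrasonic range: `mount_height - true_height` (metres) over
#' a plant, `mount_height` over bare ground, plus optional Gaussian noise.
#' The RTK fix is reported in geographic coordinates (inverse UTM of the
#' vehicle position); sensor positions are recovered downstream by
#' [project_track()].
#'
#' @param truth a `trial_truth`.
#' @param rig a [sensor_rig].
#' @param rows optional row-id subset to drive (default: all rows).
#' @param speed vehicle speed, m/s.
#' @param lead bare-ground lead distance before/after each row, metres.
#' @param start_time first timestamp (POSIXct or ISO-8601 string).
#' @return tibble with `timestamp`, `lat`, `lon`, `sensor_index`,
#'   `range_m`, one row per (fix, sensor).
#' @export
simulate_height_track <- function(truth, rig = sensor_rig(), rows = NULL,
                                  speed = 1.0, lead = 1.0,
                                  start_time = "2018-06-19T08:00:00Z") {
  stopifnot(inherits(truth, "trial_truth"))
  l <- truth$layout
  rtab <- truth$rows
  if (!is.null(rows)) rtab <- rtab[rtab$row_id %in% rows, , drop = FALSE]
  if (nrow(rtab) == 0L) {
    warning("path traverses no rows; returning an empty track", call. = FALSE)
    return(tibble::tibble(timestamp = character(), lat = numeric(),
                          lon = numeric(), sensor_index = integer(),
                          range_m = numeric()))
  }
  rtab <- dplyr::arrange(rtab, .data$block, .data$row_in_block)
  dt <- 1 / rig$sample_rate
  step <- speed * dt
  t0 <- as.POSIXct(sub("Z$", "", sub("T", " ", start_time)), tz = "UTC")

  with_seed(l$rng_seed + 3L, {
    passes <- purrr::map_dfr(seq_len(nrow(rtab)), function(i) {
      r <- rtab[i, ]
      ys <- seq(r$wy1 + lead, r$wy0 - lead, by = -step)
      tibble::tibble(pass = i, fix = seq_along(ys), x = r$center_x, y = ys)
    })
    passes$tsec <- (seq_len(nrow(passes)) - 1) * dt
    # heading due south; sensors offset to the right of travel (west)
    out <- purrr::map_dfr(seq_len(rig$n_sensors), function(s) {
      sx <- passes$x - rig$lateral_offsets[s]
      sy <- passes$y
      h <- .plant_under(truth, sx, sy)
      rng <- ifelse(is.na(h), rig$mount_height,
                    rig$mount_height - h / 100)
      tibble::tibble(pass = passes$pass, fix = passes$fix,
                     tsec = passes$tsec, x = passes$x, y = passes$y,
                     sensor_index = s, range_m = rng)
    })
    if (rig$range_noise_sd > 0) {
      out$range_m <- out$range_m + rnorm(nrow(out), 0, rig$range_noise_sd)
    }
  })
  out <- dplyr::arrange(out, .data$tsec, .data$sensor_index)
  ll <- utm_to_latlon(out$x, out$y, zone = l$zone, south = l$south)
  tibble::tibble(
    timestamp = format(t0 + out$tsec, "%Y-%m-%dT%H:%M:%OS1Z"),
    lat = ll$lat, lon = ll$lon,
    sensor_index = out$sensor_index, range_m = out$range_m
  )
}

#' Project a height track to the field CRS and locate each sensor
#'
#' RTK fixes (lat/lon) are projected to UTM; the heading at each fix comes
#' from consecutive distinct positions (stationary fixes carry the last
#' moving heading), and each sensor's position is the fix plus its lateral
#' offset rotated to the right of travel. Heights are
#' `(mount_height - range) * 100` cm, floored at 0.
#'
#' @param track tibble (or CSV path) with `timestamp`, `lat`, `lon`,
#'   `sensor_index`, `range_m`.
#' @param rig the [sensor_rig] that recorded the track.
#' @param zone,south UTM zone of the field; defaults from the first fix.
#' @return tibble of height samples: `timestamp`, `sensor_index`, `x`, `y`
#'   (sensor position, metres), `range_m`, `height_cm`.
#' @export
project_track <- function(track, rig = sensor_rig(), zone = NULL,
                          south = NULL) {
  if (is.character(track)) {
    track <- tibble::as_tibble(read.csv(track, stringsAsFactors = FALSE))
  }
  if (is.null(zone)) zone <- utm_zone(track$lon[1])
  if (is.null(south)) south <- track$lat[1] < 0
  utm <- latlon_to_utm(track$lat, track$lon, zone = zone, south = south)
  d <- dplyr::mutate(track, ve = utm$easting, vn = utm$northing)

  fixes <- dplyr::distinct(d, .data$timestamp, .data$ve, .data$vn)
  dx <- diff(fixes$ve); dy <- diff(fixes$vn)
  # heading of segment into each fix; carry last moving heading over
  # stationary duplicates; first fix uses the first moving heading
  hx <- c(dx[1], dx); hy <- c(dy[1], dy)
  still <- hx == 0 & hy == 0
  for (i in which(still)) {
    if (i > 1L) { hx[i] <- hx[i - 1L]; hy[i] <- hy[i - 1L] }
  }
  nrm <- sqrt(hx^2 + hy^2)
  nrm[nrm == 0] <- 1
  fixes$hx <- hx / nrm; fixes$hy <- hy / nrm

  d <- dplyr::left_join(d, fixes, by = c("timestamp", "ve", "vn"))
  off <- rig$lateral_offsets[d$sensor_index]
  # right-hand unit vector of heading (hx, hy) is (hy, -hx)
  tibble::tibble(
    timestamp = d$timestamp,
    sensor_index = d$sensor_index,
    x = d$ve + off * d$hy,
    y = d$vn - off * d$hx,
    range_m = d$range_m,
    height_cm = pmax(0, (rig$mount_height - d$range_m) * 100)
  )
}

#' Match height samples to plant polygons
#'
#' Point-in-polygon assignment under the half-open pixel convention, then a
#' per-plant summary (median by default; mean optional). Samples outside
#' every polygon are dropped and counted.
#'
#' Samples at or below `min_height_cm` are treated as bare-ground baseline
#' echoes (the boom sees the soil between and beside plants) and excluded
#' before aggregation; plants with only baseline samples get no height.
#'
#' @param samples tibble from [project_track()] (world `x`, `y`,
#'   `height_cm`).
#' @param polygons plant-polygon tibble (pixel rectangles with `plant_id`).
#' @param raster the [mb_raster] defining the pixel grid of `polygons`.
#' @param stat `"median"` or `"mean"`.
#' @param min_height_cm baseline filter threshold, cm (set < 0 to keep all
#'   samples).
#' @return tibble with `plant_id`, `height_cm`, `n_height_samples`.
#' @export
match_heights <- function(samples, polygons, raster,
                          stat = c("median", "mean"), min_height_cm = 1) {
  stat <- match.arg(stat)
  if (nrow(samples) == 0L) stop("no height samples in the field", call. = FALSE)
  px <- world_to_pixel(raster, samples$x, samples$y)
  col <- floor(px$col); row <- floor(px$row)
  pid <- rep(NA_character_, nrow(samples))
  for (i in seq_len(nrow(polygons))) {
    inside <- col >= polygons$x0[i] & col < polygons$x1[i] &
      row >= polygons$y0[i] & row < polygons$y1[i]
    pid[inside] <- polygons$plant_id[i]
  }
  dropped <- sum(is.na(pid))
  if (dropped > 0) {
    message(dropped, " height sample(s) fall in no polygon; dropped")
  }
  agg <- if (stat == "median") median else mean
  tibble::tibble(plant_id = pid, height_cm = samples$height_cm) |>
    dplyr::filter(!is.na(.data$plant_id),
                  .data$height_cm > min_height_cm) |>
    dplyr::group_by(.data$plant_id) |>
    dplyr::summarise(height_cm = agg(.data$height_cm),
                     n_height_samples = dplyr::n(), .groups = "drop")
}
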