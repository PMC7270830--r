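# Per-plant trait extraction: zonal NDVI statistics over plant polygons and
# the combined NDVI-squared x height predictor.

#' Zonal NDVI statistics per plant polygon
#'
#' Aggregates the pixels whose centres fall inside each half-open polygon
#' rectangle; nodata/NA pixels are excluded. Polygons with no valid pixel
#' are flagged.
#'
#' @param ndvi NDVI matrix or single-band [mb_raster].
#' @param polygons plant-polygon tibble (0-based half-open `x0`,`x1`,
#'   `y0`,`y1`, plus `plant_id`).
#' @return tibble with `plant_id`, `ndvi_mean`, `ndvi_median`, `ndvi_max`,
#'   `n_ndvi_pixels`, `flag_no_pixels`.
#' @export
extract_ndvi_stats <- function(ndvi, polygons) {
  m <- if (inherits(ndvi, "mb_raster")) raster_band(ndvi, names(ndvi$bands)[1]) else ndvi
  H <- nrow(m); W <- ncol(m)
  if (any(polygons$x0 < 0 | polygons$y0 < 0 |
          polygons$x1 > W | polygons$y1 > H)) {
    stop("polygon extends outside the raster", call. = FALSE)
  }
  n <- nrow(polygons)
  mu <- md <- mx <- rep(NA_real_, n)
  np <- integer(n)
  for (i in seq_len(n)) {
    px <- m[(polygons$y0[i] + 1L):polygons$y1[i],
            (polygons$x0[i] + 1L):polygons$x1[i]]
    px <- px[!is.na(px)]
    np[i] <- length(px)
    if (np[i] > 0L) {
      mu[i] <- mean(px); md[i] <- median(px); mx[i] <- max(px)
    }
  }
  if (any(np == 0L)) {
    message(sum(np == 0L), " polygon(s) contain no valid pixels (flagged)")
  }
  tibble::tibble(plant_id = polygons$plant_id, ndvi_mean = mu,
                 ndvi_median = md, ndvi_max = mx, n_ndvi_pixels = np,
                 flag_no_pixels = np == 0L)
}

#' Combined NDVI/height biomass predictor
#'
#' The default definition is `NDVI^2 * height_cm`; the exponent is
#' configurable and the active definition is recorded in the
#' `predictor_definition` attribute (and by callers in output files).
#' Records missing either trait get `NA`.
#'
#' @param ndvi NDVI statistic (dimensionless, vector).
#' @param height_cm plant height, cm (vector).
#' @param exponent NDVI exponent (default 2).
#' @return numeric vector with a `predictor_definition` attribute.
#' @export
compute_predictor <- function(ndvi, height_cm, exponent = 2) {
  out <- ndvi^exponent * height_cm
  attr(out, "predictor_definition") <-
    sprintf("ndvi^%g * height_cm", exponent)
  out
}

#' Assemble the per-plant trait table
#'
#' Joins NDVI statistics and heights, computes the combined predictor and
#' flags incomplete records (no prediction is attempted for them).
#'
#' @param ndvi_stats tibble from [extract_ndvi_stats()].
#' @param heights tibble from [match_heights()], or `NULL` when no track
#'   is available.
#' @param exponent NDVI exponent for [compute_predictor()].
#' @return trait tibble with `ndvisq_ph` and `flag` columns.
#' @export
build_trait_records <- function(ndvi_stats, heights = NULL, exponent = 2) {
  out <- ndvi_stats
  if (is.null(heights)) {
    out$height_cm <- NA_real_
    out$n_height_samples <- 0L
  } else {
    out <- dplyr::left_join(out, heights, by = "plant_id")
    out$n_height_samples[is.na(out$n_height_samples)] <- 0L
  }
  out$ndvisq_ph <- compute_predictor(out$ndvi_mean, out$height_cm, exponent)
  out$flag <- dplyr::case_when(
    out$flag_no_pixels ~ "no-ndvi-pixels",
    is.na(out$height_cm) ~ "no-height",
    .default = "ok"
  )
  attr(out, "predictor_definition") <-
    attr(out$ndvisq_ph, "predictor_definition")
  out
}
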