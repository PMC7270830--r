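#' Render a synthetic multiband ortho-mosaic of a trial
#'
#' Plants are drawn as radially decaying (Gaussian) canopy blobs on a bare
#' soil background. The blob peak equals the plant's `true_ndvi` exactly at
#' the pixel nearest its centre (the per-axis profile is normalised to its
#' on-grid maximum) and decays to soil with distance; blobs are truncated at
#' `cutoff_sigma` standard deviations, where the Gaussian is already
#' negligible, so soil between rows is exactly uniform. Overlapping blobs
#' combine by pixel-wise maximum so peaks stay exact.
#'
#' Reflectance is derived per band from the NDVI field with a constant NIR
#' reflectance (red follows by NDVI inversion), then digital numbers follow
#' the inverse of the empirical-line map `reflectance_pct = gain * DN +
#' offset`, optionally plus Gaussian sensor noise. Calibration panels of
#' known reflectance and nine ground-control markers (spectrally flat
#' squares) are placed in the soil margin outside the plots.
#'
#' @param truth a `trial_truth` from [generate_layout()].
#' @param bands band subset to render (of blue/green/red/rededge/nir); red
#'   and nir are always included.
#' @param noise_sd Gaussian DN noise standard deviation (0 = noiseless).
#' @param gain,offset empirical-line coefficients used to invert reflectance
#'   into DN, recycled across bands (percent reflectance per DN; percent).
#' @param nir_reflectance NIR reflectance of vegetation and soil (fraction).
#' @param soil_ndvi soil background NDVI; default a single per-render draw
#'   from U(0.05, 0.15).
#' @param soil_texture_sd per-pixel NDVI texture noise on soil (default 0,
#'   spatially uniform soil).
#' @param cutoff_sigma blob truncation radius in Gaussian SD units.
#' @param render_markers render the GCP marker squares into the imagery.
#' @param max_pixels guard against accidentally huge rasters.
#' @return list with `raster` (DN bands, [mb_raster]), `ndvi_truth`
#'   (single-band [mb_raster]), `panels` and `gcps` tibbles, `calibration`
#'   (the gain/offset used per band) and `soil_ndvi`.
#' @export
render_ortho <- function(truth, bands = c("red", "nir"), noise_sd = 0,
                         gain = 0.1, offset = 0, nir_reflectance = 0.40,
                         soil_ndvi = NULL, soil_texture_sd = 0,
                         cutoff_sigma = 4, render_markers = TRUE,
                         max_pixels = 6e7) {
  stopifnot(inherits(truth, "trial_truth"))
  l <- truth$layout
  g <- layout_geometry(l)
  bands <- union(c("red", "nir"), bands)
  bands <- names(band_wavelengths)[names(band_wavelengths) %in% bands]

  gsd <- l$gsd
  W <- as.integer(round((g$trial_w + 2 * l$margin) / gsd))
  H <- as.integer(round((g$trial_h + 2 * l$margin) / gsd))
  if (as.numeric(W) * H > max_pixels) {
    stop(sprintf("render of %d x %d px exceeds max_pixels = %g", H, W,
                 max_pixels), call. = FALSE)
  }
  x0 <- g$x0 - l$margin   # world coords of raster top-left corner
  y0 <- g$y1 + l$margin

  with_seed(l$rng_seed + 2L, {
    if (is.null(soil_ndvi)) soil_ndvi <- runif(1, 0.05, 0.15)
    ndvi <- matrix(soil_ndvi, H, W)
    if (soil_texture_sd > 0) {
      ndvi <- ndvi + matrix(rnorm(H * W, 0, soil_texture_sd), H, W)
    }

    # paint plant blobs (pixel-wise max with current canvas)
    xs <- x0 + (seq_len(W) - 0.5) * gsd   # pixel-centre world coords
    ys <- y0 - (seq_len(H) - 0.5) * gsd
    p <- truth$plants
    for (i in seq_len(nrow(p))) {
      sig <- p$radius[i] / 2
      halfw <- cutoff_sigma * sig
      ci <- which(xs >= p$x[i] - halfw & xs <= p$x[i] + halfw)
      ri <- which(ys >= p$y[i] - halfw & ys <= p$y[i] + halfw)
      if (!length(ci) || !length(ri)) next
      ex <- exp(-(xs[ci] - p$x[i])^2 / (2 * sig^2))
      ey <- exp(-(ys[ri] - p$y[i])^2 / (2 * sig^2))
      w <- (ey / max(ey)) %o% (ex / max(ex))
      blob <- soil_ndvi + (p$true_ndvi[i] - soil_ndvi) * w
      ndvi[ri, ci] <- pmax(ndvi[ri, ci], blob)
    }

    # calibration panels: 1 m squares in the northern soil margin
    panel_refl <- c(6, 11, 22, 33)
    # panel edge length: 1 m when the northern margin strip has room,
    # smaller (down to 10 px) on miniature layouts; panels sit at the top
    # of the margin, clear of the GCP markers near the crop boundary
    ps <- max(10 * gsd,
              min(1, (g$trial_w + 2 * l$margin - 1) / (2 * length(panel_refl)),
                  l$margin - l$crop_margin - 0.30 - 3 * gsd))
    panel_y1 <- g$y1 + l$margin - 2 * gsd              # panel top (north)
    pwx0 <- g$x0 - l$margin + 0.5 + (seq_along(panel_refl) - 1) * 2 * ps
    panels <- tibble::tibble(
      panel_id = sprintf("panel-%02d", seq_along(panel_refl)),
      reflectance_pct = panel_refl,
      wx0 = pwx0,
      wx1 = pwx0 + ps,
      wy1 = panel_y1,
      wy0 = panel_y1 - ps
    )
    rx0 <- x0; ry0 <- y0
    panels <- dplyr::mutate(
      panels,
      x0 = round((.data$wx0 - rx0) / gsd),
      x1 = round((.data$wx1 - rx0) / gsd),
      y0 = round((ry0 - .data$wy1) / gsd),
      y1 = round((ry0 - .data$wy0) / gsd)
    )

    # nine GCPs: four crop corners, four crop mid-edges, one margin point
    cm <- l$crop_margin
    cx0 <- g$x0 - cm; cx1 <- g$x1 + cm
    cy1 <- g$y1 + cm; cy0 <- g$y0 - cm
    # corner GCPs sit on the crop boundary; the others are pushed outward
    # so their markers lie wholly outside the rectified area of interest
    mo <- 0.35
    gcps <- tibble::tibble(
      id = c("c-nw", "c-ne", "c-se", "c-sw",
             "m-n", "m-e", "m-s", "m-w", "m-x"),
      world_x = c(cx0, cx1, cx1, cx0,
                  (cx0 + cx1) / 2, cx1 + mo, (cx0 + cx1) / 2, cx0 - mo,
                  cx1 + min(1.0, l$margin - cm) / 2),
      world_y = c(cy1, cy1, cy0, cy0,
                  cy1 + mo, (cy0 + cy1) / 2, cy0 - mo, (cy0 + cy1) / 2,
                  cy0 - min(1.0, l$margin - cm) / 2)
    ) |>
      dplyr::mutate(pixel_col = (.data$world_x - x0) / gsd,
                    pixel_row = (y0 - .data$world_y) / gsd)

    # stamp spectrally flat targets: NDVI 0 (equal red/NIR reflectance)
    stamp <- function(m, wx0, wx1, wy0, wy1, value) {
      c0 <- max(1L, as.integer(floor((wx0 - x0) / gsd)) + 1L)
      c1 <- min(W, as.integer(ceiling((wx1 - x0) / gsd)))
      r0 <- max(1L, as.integer(floor((y0 - wy1) / gsd)) + 1L)
      r1 <- min(H, as.integer(ceiling((y0 - wy0) / gsd)))
      if (c0 <= c1 && r0 <= r1) m[r0:r1, c0:c1] <- value
      m
    }
    # flat-target reflectance per target, carried alongside NDVI
    flat <- matrix(NA_real_, H, W)
    for (i in seq_len(nrow(panels))) {
      flat <- stamp(flat, panels$wx0[i], panels$wx1[i], panels$wy0[i],
                    panels$wy1[i], panels$reflectance_pct[i] / 100)
      ndvi <- stamp(ndvi, panels$wx0[i], panels$wx1[i], panels$wy0[i],
                    panels$wy1[i], 0)
    }
    if (render_markers) {
      for (i in seq_len(nrow(gcps))) {
        flat <- stamp(flat, gcps$world_x[i] - 0.25, gcps$world_x[i] + 0.25,
                      gcps$world_y[i] - 0.25, gcps$world_y[i] + 0.25, 0.44)
        ndvi <- stamp(ndvi, gcps$world_x[i] - 0.25, gcps$world_x[i] + 0.25,
                      gcps$world_y[i] - 0.25, gcps$world_y[i] + 0.25, 0)
      }
    }

    # band reflectance from NDVI (constant-NIR model), then DN
    calib <- tibble::tibble(band = bands,
                            gain = rep_len(gain, length(bands)),
                            offset = rep_len(offset, length(bands)))
    red <- nir_reflectance * (1 - ndvi) / (1 + ndvi)
    isflat <- !is.na(flat)
    dn <- list()
    for (b in bands) {
      refl <- switch(b,
        nir = matrix(nir_reflectance, H, W),
        red = red,
        green = red + 0.25 * (nir_reflectance - red),
        rededge = red + 0.60 * (nir_reflectance - red),
        blue = 0.8 * red
      )
      refl[isflat] <- flat[isflat]
      gn <- calib$gain[calib$band == b]
      of <- calib$offset[calib$band == b]
      m <- (100 * refl - of) / gn
      if (noise_sd > 0) m <- m + matrix(rnorm(H * W, 0, noise_sd), H, W)
      dn[[b]] <- m
    }
  })

  raster <- mb_raster(dn, x0 = x0, y0 = y0, gsd = gsd, crs = l$crs,
                      wavelengths = band_wavelengths[bands])
  ndvi_truth <- mb_raster(list(ndvi = ndvi), x0 = x0, y0 = y0, gsd = gsd,
                          crs = l$crs)
  list(raster = raster, ndvi_truth = ndvi_truth, panels = panels,
       gcps = gcps, calibration = calib, soil_ndvi = soil_ndvi)
}
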