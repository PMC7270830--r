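# Empirical-line radiometric calibration: per band, an ordinary
# least-squares line mapping digital numbers to percent reflectance fitted
# on panels of known reflectance, then applied to the full raster.

#' Panel observations from a raster
#'
#' Computes the mean digital number of every band over every panel region.
#'
#' @param raster DN [mb_raster].
#' @param panels tibble with `panel_id`, `reflectance_pct` and 0-based
#'   half-open pixel boxes `x0`,`x1`,`y0`,`y1`.
#' @param trim optional fraction of extreme pixels trimmed from each tail
#'   before averaging (robustness to panel-edge pixels).
#' @return tibble with `band`, `panel_id`, `reflectance_pct`, `mean_dn`.
#' @export
panel_observations <- function(raster, panels, trim = 0) {
  purrr::map_dfr(names(raster$bands), function(b) {
    m <- raster_band(raster, b)
    purrr::map_dfr(seq_len(nrow(panels)), function(i) {
      p <- panels[i, ]
      px <- m[(p$y0 + 1L):p$y1, (p$x0 + 1L):p$x1]
      tibble::tibble(band = b, panel_id = p$panel_id,
                     reflectance_pct = p$reflectance_pct,
                     mean_dn = mean(px, trim = trim, na.rm = TRUE))
    })
  })
}

#' Fit the empirical line per band
#'
#' Ordinary least squares of percent reflectance on mean panel DN:
#' `reflectance_pct = gain * DN + offset`, reported with the fit R-squared.
#'
#' @param observations tibble with `band`, `reflectance_pct`, `mean_dn`
#'   (>= 2 panels with distinct DN per band).
#' @return tibble with one row per band: `gain`, `offset`, `r_squared`,
#'   `n_panels`.
#' @export
fit_calibration <- function(observations) {
  observations |>
    dplyr::group_by(.data$band) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 2L || length(unique(d$mean_dn)) < 2L) {
        stop(sprintf(paste0("cannot fit calibration for band '%s': need >= 2 ",
                            "panels with distinct DN"), key$band),
             call. = FALSE)
      }
      fit <- lm(reflectance_pct ~ mean_dn, data = d)
      sst <- sum((d$reflectance_pct - mean(d$reflectance_pct))^2)
      r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
      tibble::tibble(gain = coef(fit)[[2]], offset = coef(fit)[[1]],
                     r_squared = r2, n_panels = nrow(d))
    }) |>
    dplyr::ungroup()
}

#' Apply band calibrations to a DN raster
#'
#' Converts DN to reflectance fraction `(gain * DN + offset) / 100`,
#' clipping to the physical range 0-1 (clip counts reported via the
#' `clipped` attribute) and preserving nodata.
#'
#' @param raster DN [mb_raster].
#' @param calibration tibble from [fit_calibration()] (must cover every
#'   requested band).
#' @param bands bands to convert (default: all in the raster).
#' @return reflectance [mb_raster] (fractions), with a `clipped` attribute
#'   counting clipped pixels per band.
#' @export
apply_calibration <- function(raster, calibration, bands = names(raster$bands)) {
  missing_b <- setdiff(bands, calibration$band)
  if (length(missing_b)) {
    stop("no calibration for band(s): ", paste(missing_b, collapse = ", "),
         call. = FALSE)
  }
  clipped <- integer(0)
  out <- lapply(bands, function(b) {
    g <- calibration$gain[calibration$band == b]
    o <- calibration$offset[calibration$band == b]
    m <- raster$bands[[b]]
    nd <- m == raster$nodata
    r <- (g * m + o) / 100
    nclip <- sum((r < 0 | r > 1) & !nd, na.rm = TRUE)
    r <- clamp(r, 0, 1)
    r[nd] <- raster$nodata
    clipped[[b]] <<- nclip
    r
  })
  names(out) <- bands
  res <- mb_raster(out, raster$x0, raster$y0, raster$gsd, crs = raster$crs,
                   nodata = raster$nodata,
                   wavelengths = raster$wavelengths[bands])
  attr(res, "clipped") <- clipped
  res
}

#' Compute NDVI from red and NIR reflectance
#'
#' `NDVI = (NIR - Red) / (NIR + Red)`; pixels where the denominator is 0
#' (or either input is nodata) become nodata.
#'
#' @param red,nir reflectance matrices of equal dimensions, or a
#'   reflectance [mb_raster] with `red` and `nir` bands as `red` (then
#'   `nir` is ignored).
#' @return NDVI as a matrix (matrix input) or single-band [mb_raster].
#' @export
compute_ndvi <- function(red, nir = NULL) {
  if (inherits(red, "mb_raster")) {
    rr <- red
    m <- compute_ndvi(raster_band(rr, "red"), raster_band(rr, "nir"))
    m[is.na(m)] <- rr$nodata
    return(mb_raster(list(ndvi = m), rr$x0, rr$y0, rr$gsd, crs = rr$crs,
                     nodata = rr$nodata))
  }
  if (!all(dim(red) == dim(nir))) {
    stop("red and nir shapes differ", call. = FALSE)
  }
  den <- nir + red
  out <- (nir - red) / den
  out[den == 0] <- NA_real_
  out
}
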