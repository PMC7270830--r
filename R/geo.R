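# Transverse-Mercator (UTM) projection on the WGS84 ellipsoid.
# Standard series expansion (sub-millimetre within a zone); implemented here
# because no projection library ships with the package's dependency set.

.wgs84 <- list(a = 6378137, f = 1 / 298.257223563)

#' UTM zone number for a longitude
#' @param lon longitude in degrees.
#' @return integer zone number 1-60.
#' @export
utm_zone <- function(lon) as.integer(floor((lon + 180) / 6) %% 60 + 1)

#' EPSG code string for a UTM zone
#' @param zone zone number.
#' @param south logical, southern hemisphere.
#' @return e.g. `"EPSG:32754"`.
#' @export
utm_epsg <- function(zone, south = TRUE) {
  sprintf("EPSG:%d", (if (south) 32700L else 32600L) + as.integer(zone))
}

.parse_utm_crs <- function(crs) {
  m <- regmatches(crs, regexec("^EPSG:(326|327)([0-9]{2})$", crs))[[1]]
  if (length(m) != 3L) stop("not a UTM EPSG code: ", crs, call. = FALSE)
  list(zone = as.integer(m[3]), south = m[2] == "327")
}

#' Project geographic coordinates to UTM
#'
#' @param lat,lon degrees (vectors).
#' @param zone UTM zone; defaults to the zone of the first longitude.
#' @param south southern-hemisphere false northing (default TRUE).
#' @return tibble with `easting`, `northing` (metres), plus `zone`, `crs`.
#' @export
latlon_to_utm <- function(lat, lon, zone = NULL, south = lat[1] < 0) {
  if (is.null(zone)) zone <- utm_zone(lon[1])
  lon0 <- (zone - 1) * 6 - 180 + 3
  if (any(abs(lon - lon0) > 9)) {
    stop(sprintf(paste0("longitude outside validity range of UTM zone %d ",
                        "(central meridian %d): consider zone %d"),
                 zone, lon0, utm_zone(lon[which.max(abs(lon - lon0))])),
         call. = FALSE)
  }
  a <- .wgs84$a; f <- .wgs84$f; k0 <- 0.9996
  e2 <- f * (2 - f); ep2 <- e2 / (1 - e2)
  phi <- lat * pi / 180
  dlam <- (lon - lon0) * pi / 180
  sp <- sin(phi); cp <- cos(phi); tp <- tan(phi)
  N <- a / sqrt(1 - e2 * sp^2)
  T <- tp^2
  C <- ep2 * cp^2
  A <- cp * dlam
  M <- a * ((1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256) * phi -
            (3 * e2 / 8 + 3 * e2^2 / 32 + 45 * e2^3 / 1024) * sin(2 * phi) +
            (15 * e2^2 / 256 + 45 * e2^3 / 1024) * sin(4 * phi) -
            (35 * e2^3 / 3072) * sin(6 * phi))
  x <- k0 * N * (A + (1 - T + C) * A^3 / 6 +
                 (5 - 18 * T + T^2 + 72 * C - 58 * ep2) * A^5 / 120) + 500000
  y <- k0 * (M + N * tp * (A^2 / 2 + (5 - T + 9 * C + 4 * C^2) * A^4 / 24 +
             (61 - 58 * T + T^2 + 600 * C - 330 * ep2) * A^6 / 720))
  if (south) y <- y + 1e7
  tibble::tibble(easting = x, northing = y, zone = zone,
                 crs = utm_epsg(zone, south))
}

#' Inverse UTM projection
#'
#' @param easting,northing metres.
#' @param zone UTM zone number.
#' @param south logical, whether `northing` carries the southern false
#'   northing.
#' @return tibble with `lat`, `lon` in degrees.
#' @export
utm_to_latlon <- function(easting, northing, zone, south = TRUE) {
  a <- .wgs84$a; f <- .wgs84$f; k0 <- 0.9996
  e2 <- f * (2 - f); ep2 <- e2 / (1 - e2)
  e1 <- (1 - sqrt(1 - e2)) / (1 + sqrt(1 - e2))
  lon0 <- (zone - 1) * 6 - 180 + 3
  x <- easting - 500000
  y <- if (south) northing - 1e7 else northing
  M <- y / k0
  mu <- M / (a * (1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256))
  phi1 <- mu + (3 * e1 / 2 - 27 * e1^3 / 32) * sin(2 * mu) +
    (21 * e1^2 / 16 - 55 * e1^4 / 32) * sin(4 * mu) +
    (151 * e1^3 / 96) * sin(6 * mu) +
    (1097 * e1^4 / 512) * sin(8 * mu)
  sp <- sin(phi1); cp <- cos(phi1); tp <- tan(phi1)
  C1 <- ep2 * cp^2
  T1 <- tp^2
  N1 <- a / sqrt(1 - e2 * sp^2)
  R1 <- a * (1 - e2) / (1 - e2 * sp^2)^1.5
  D <- x / (N1 * k0)
  phi <- phi1 - (N1 * tp / R1) *
    (D^2 / 2 - (5 + 3 * T1 + 10 * C1 - 4 * C1^2 - 9 * ep2) * D^4 / 24 +
     (61 + 90 * T1 + 298 * C1 + 45 * T1^2 - 252 * ep2 - 3 * C1^2) * D^6 / 720)
  lam <- (D - (1 + 2 * T1 + C1) * D^3 / 6 +
          (5 - 2 * C1 + 28 * T1 - 3 * C1^2 + 8 * ep2 + 24 * T1^2) * D^5 / 120) / cp
  tibble::tibble(lat = phi * 180 / pi, lon = lon0 + lam * 180 / pi)
}
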