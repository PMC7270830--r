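# Minimal GeoJSON export/import for rectangle polygons and point features.
# Rectangles are carried in tables as half-open pixel boxes [x0,x1) x [y0,y1)
# and exported as closed world-coordinate rings via the raster geotransform.

#' Write rectangle polygons to GeoJSON
#'
#' Each row of `rects` must carry half-open pixel bounds `x0`, `x1`, `y0`,
#' `y1` (0-based, x = column, y = row). All other columns become feature
#' properties. Coordinates are exported in the raster's world CRS.
#'
#' @param rects tibble of rectangles + attributes.
#' @param raster the [mb_raster] the pixel coordinates refer to.
#' @param path output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_polygons_geojson <- function(rects, raster, path) {
  props <- setdiff(names(rects), c("x0", "x1", "y0", "y1"))
  feats <- lapply(seq_len(nrow(rects)), function(i) {
    r <- rects[i, ]
    cs <- pixel_to_world(raster,
                         col = c(r$x0, r$x1, r$x1, r$x0, r$x0),
                         row = c(r$y0, r$y0, r$y1, r$y1, r$y0))
    list(
      type = "Feature",
      properties = as.list(r[props]),
      geometry = list(type = "Polygon",
                      coordinates = list(Map(c, cs$x, cs$y)))
    )
  })
  gj <- list(type = "FeatureCollection",
             crs = list(type = "name",
                        properties = list(name = raster$crs)),
             features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write point features to GeoJSON
#'
#' @param pts tibble with pixel columns `col`, `row` (0-based centres) plus
#'   attribute columns.
#' @inheritParams write_polygons_geojson
#' @return `path`, invisibly.
#' @export
write_points_geojson <- function(pts, raster, path) {
  props <- setdiff(names(pts), c("col", "row"))
  w <- pixel_to_world(raster, pts$col, pts$row, offset = 0.5)
  feats <- lapply(seq_len(nrow(pts)), function(i) {
    list(type = "Feature",
         properties = as.list(pts[i, props]),
         geometry = list(type = "Point", coordinates = c(w$x[i], w$y[i])))
  })
  gj <- list(type = "FeatureCollection",
             crs = list(type = "name",
                        properties = list(name = raster$crs)),
             features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read features written by the GeoJSON writers back into a tibble
#'
#' Rectangle polygons come back with world-coordinate bounds `wx0`, `wx1`,
#' `wy0`, `wy1`; points with `x`, `y`. Properties become columns.
#'
#' @param path `.geojson` path.
#' @return tibble.
#' @export
read_features_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  rows <- purrr::map(gj$features, function(f) {
    p <- tibble::as_tibble(lapply(f$properties, function(v) {
      if (is.null(v)) NA else v
    }))
    if (f$geometry$type == "Polygon") {
      ring <- f$geometry$coordinates[[1]]
      xs <- purrr::map_dbl(ring, 1); ys <- purrr::map_dbl(ring, 2)
      dplyr::bind_cols(p, tibble::tibble(wx0 = min(xs), wx1 = max(xs),
                                         wy0 = min(ys), wy1 = max(ys)))
    } else {
      dplyr::bind_cols(p, tibble::tibble(x = f$geometry$coordinates[[1]],
                                         y = f$geometry$coordinates[[2]]))
    }
  })
  dplyr::bind_rows(rows)
}
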