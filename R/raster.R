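#' Multiband georeferenced raster
#'
#' A lightweight in-memory container for a stack of co-registered raster
#' bands: a named list of numeric matrices (rows = image rows, top row =
#' north), a north-up affine geotransform, a CRS identifier and a nodata
#' value. Pixel coordinates are 0-based `(col, row)`; the centre of pixel
#' `(0, 0)` sits at `(x0 + gsd/2, y0 - gsd/2)` in world coordinates.
#'
#' @param bands named list of numeric matrices, all the same dimension.
#' @param x0,y0 world coordinates (metres) of the top-left corner of the
#'   top-left pixel.
#' @param gsd ground sampling distance, metres per pixel.
#' @param crs CRS identifier string, e.g. `"EPSG:32754"`.
#' @param nodata nodata sentinel value (default -9999).
#' @param wavelengths optional named numeric vector of band centre
#'   wavelengths in nm.
#' @return an object of class `mb_raster`.
#' @export
mb_raster <- function(bands, x0, y0, gsd, crs = "EPSG:32754",
                      nodata = -9999, wavelengths = NULL) {
  if (!is.list(bands) || is.null(names(bands)) || any(names(bands) == "")) {
    stop("`bands` must be a named list of matrices", call. = FALSE)
  }
  dims <- unique(lapply(bands, dim))
  if (length(dims) != 1L) {
    stop("all bands must share the same dimensions", call. = FALSE)
  }
  structure(
    list(bands = bands, x0 = x0, y0 = y0, gsd = gsd, crs = crs,
         nodata = nodata, wavelengths = wavelengths),
    class = "mb_raster"
  )
}

#' @export
print.mb_raster <- function(x, ...) {
  d <- dim(x$bands[[1]])
  cat(sprintf("<mb_raster> %d x %d px, %d band(s): %s\n", d[1], d[2],
              length(x$bands), paste(names(x$bands), collapse = ", ")))
  cat(sprintf("  origin (%.3f, %.3f), gsd %.4g m/px, crs %s, nodata %s\n",
              x$x0, x$y0, x$gsd, x$crs, format(x$nodata)))
  invisible(x)
}

#' @export
dim.mb_raster <- function(x) dim(x$bands[[1]])

#' Centre wavelengths (nm) of the five-band multispectral sensor emulated by
#' the synthetic generator: blue 465-485, green 550-570, red 663-673,
#' red-edge 712-722, NIR 820-860.
#' @export
band_wavelengths <- c(blue = 475, green = 560, red = 668,
                      rededge = 717, nir = 840)

#' Convert pixel coordinates to world coordinates
#'
#' Maps 0-based pixel corners: `(col, row) = (0, 0)` returns the raster
#' origin (the geotransform translation terms). Use `offset = 0.5` for
#' pixel centres.
#'
#' @param raster an [mb_raster].
#' @param col,row numeric vectors of 0-based pixel coordinates.
#' @param offset sub-pixel offset added to both coordinates before the
#'   affine map (0 = corner, 0.5 = centre).
#' @return tibble with columns `x`, `y` (world metres).
#' @export
pixel_to_world <- function(raster, col, row, offset = 0) {
  tibble::tibble(
    x = raster$x0 + (col + offset) * raster$gsd,
    y = raster$y0 - (row + offset) * raster$gsd
  )
}

#' Convert world coordinates to (fractional) pixel coordinates
#'
#' Exact inverse of [pixel_to_world()]: forward then inverse round-trips to
#' within 1e-9 m for any in-range coordinate.
#'
#' @inheritParams pixel_to_world
#' @param x,y world coordinates (metres).
#' @return tibble with columns `col`, `row` (0-based, fractional).
#' @export
world_to_pixel <- function(raster, x, y, offset = 0) {
  tibble::tibble(
    col = (x - raster$x0) / raster$gsd - offset,
    row = (raster$y0 - y) / raster$gsd - offset
  )
}

#' Write a multiband raster to disk
#'
#' Band-sequential float32 binary (`<path>.dat`) plus a JSON text header
#' (`<path>.hdr.json`) recording dimensions, band labels, wavelengths,
#' geotransform, CRS and nodata. Values survive a round-trip exactly at
#' float32 precision; the header round-trips bit-exactly.
#'
#' @param raster an [mb_raster].
#' @param path output path; the `.dat`/`.hdr.json` suffixes are appended
#'   (an existing `.dat` suffix is stripped first).
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "mb_raster"))
  base <- sub("\\.dat$", "", path)
  d <- dim(raster$bands[[1]])
  hdr <- list(
    format = "phenorow-bsq-float32",
    nrow = d[1], ncol = d[2],
    bands = names(raster$bands),
    wavelengths_nm = raster$wavelengths,
    x0 = raster$x0, y0 = raster$y0, gsd = raster$gsd,
    crs = raster$crs, nodata = raster$nodata,
    byte_order = "little"
  )
  jsonlite::write_json(hdr, paste0(base, ".hdr.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(paste0(base, ".dat"), "wb")
  on.exit(close(con))
  for (b in raster$bands) {
    # column-major, matching R matrix layout
    writeBin(as.numeric(b), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read a multiband raster written by [write_raster()]
#'
#' @param path path as given to [write_raster()].
#' @return an [mb_raster].
#' @export
read_raster <- function(path) {
  base <- sub("\\.dat$", "", path)
  hpath <- paste0(base, ".hdr.json")
  dpath <- paste0(base, ".dat")
  if (!file.exists(dpath)) stop("raster data file not found: ", dpath, call. = FALSE)
  if (!file.exists(hpath)) {
    stop("raster header not found (missing geotransform): ", hpath, call. = FALSE)
  }
  hdr <- jsonlite::read_json(hpath, simplifyVector = TRUE)
  for (fld in c("x0", "y0", "gsd", "crs")) {
    if (is.null(hdr[[fld]])) {
      stop(sprintf("raster header is missing required field '%s'", fld),
           call. = FALSE)
    }
  }
  n <- hdr$nrow * hdr$ncol
  con <- file(dpath, "rb")
  on.exit(close(con))
  bands <- lapply(hdr$bands, function(b) {
    matrix(readBin(con, "numeric", n = n, size = 4L, endian = "little"),
           nrow = hdr$nrow, ncol = hdr$ncol)
  })
  names(bands) <- hdr$bands
  wl <- hdr$wavelengths_nm
  if (!is.null(wl)) wl <- unlist(wl)
  mb_raster(bands, as.numeric(hdr$x0), as.numeric(hdr$y0),
            as.numeric(hdr$gsd), crs = hdr$crs,
            nodata = as.numeric(hdr$nodata), wavelengths = wl)
}

#' Extract one band as a matrix, with nodata replaced by NA
#' @param raster an [mb_raster].
#' @param band band name.
#' @return numeric matrix.
#' @export
raster_band <- function(raster, band) {
  if (!band %in% names(raster$bands)) {
    stop("raster has no band named '", band, "'", call. = FALSE)
  }
  m <- raster$bands[[band]]
  m[m == raster$nodata] <- NA_real_
  m
}
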