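# GCP-based perspective rectification: a homography estimated from four
# corner ground-control points maps the rectified, axis-aligned output grid
# back into the source image.

# direct linear transform from 4 exact correspondences (src -> dst)
homography_from_points <- function(src, dst) {
  stopifnot(nrow(src) == 4L, nrow(dst) == 4L)
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u; b[2 * i] <- v
  }
  h <- tryCatch(solve(A, b), error = function(e) {
    stop("degenerate corner configuration (collinear points?)", call. = FALSE)
  })
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

apply_homography <- function(H, x, y) {
  w <- H[3, 1] * x + H[3, 2] * y + H[3, 3]
  list(x = (H[1, 1] * x + H[1, 2] * y + H[1, 3]) / w,
       y = (H[2, 1] * x + H[2, 2] * y + H[2, 3]) / w)
}

# signed area test: the 4 corners must form a convex, non-degenerate quad
check_convex_quad <- function(pts) {
  n <- 4L
  cr <- numeric(n)
  for (i in seq_len(n)) {
    a <- pts[i, ]; b <- pts[i %% n + 1L, ]; c <- pts[(i + 1L) %% n + 1L, ]
    cr[i] <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  }
  if (any(abs(cr) < 1e-9) || !(all(cr > 0) || all(cr < 0))) {
    stop("corner GCPs must form a convex quadrilateral (got collinear or concave corners)",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Rectify a raster onto an axis-aligned world grid from 4 corner GCPs
#'
#' The four corners (world + source-pixel coordinates) define the area of
#' interest; the output is an axis-aligned north-up grid at the raster's
#' GSD covering their world bounding box, resampled through the estimated
#' homography (nearest-neighbour by default, preserving NDVI extrema;
#' bilinear optional). When the homography is an integer pixel translation
#' the source block is copied directly. The returned mapping functions
#' convert between rectified and source pixel coordinates, so polygons
#' found in rectified space can be reported in original raster and world
#' coordinates.
#'
#' @param raster an [mb_raster].
#' @param corner_gcps tibble with 4 rows: `world_x`, `world_y`,
#'   `pixel_col`, `pixel_row` (continuous 0-based source pixel
#'   coordinates).
#' @param resample `"nearest"` or `"bilinear"`.
#' @param chunk_rows output rows processed per chunk (memory bound).
#' @return list with `raster` (rectified), `H` (rectified px -> source px),
#'   `to_source(col, row)` and `to_rectified(col, row)` mapping functions.
#' @export
perspective_transform <- function(raster, corner_gcps,
                                  resample = c("nearest", "bilinear"),
                                  chunk_rows = 512L) {
  resample <- match.arg(resample)
  stopifnot(nrow(corner_gcps) == 4L)
  src <- cbind(corner_gcps$pixel_col, corner_gcps$pixel_row)
  check_convex_quad(src)
  gsd <- raster$gsd
  wx <- corner_gcps$world_x; wy <- corner_gcps$world_y
  minx <- min(wx); maxy <- max(wy)
  Wc <- as.integer(round((max(wx) - minx) / gsd))
  Hc <- as.integer(round((maxy - min(wy)) / gsd))
  dst <- cbind((wx - minx) / gsd, (maxy - wy) / gsd)
  # homography from rectified continuous pixels to source continuous pixels
  H <- homography_from_points(dst, src)

  is_translation <- all(abs(H[c(2, 3, 4, 6)]) < 1e-9) &&
    abs(H[1, 1] - 1) < 1e-9 && abs(H[2, 2] - 1) < 1e-9
  off <- c(H[1, 3], H[2, 3])
  int_shift <- is_translation && all(abs(off - round(off)) < 1e-6)

  nrs <- nrow(raster$bands[[1]]); ncs <- ncol(raster$bands[[1]])
  nd <- raster$nodata
  out_bands <- lapply(raster$bands, function(m) {
    if (int_shift) {
      oc <- as.integer(round(off[1])); orr <- as.integer(round(off[2]))
      res <- matrix(nd, Hc, Wc)
      r_src <- (1L + orr):(Hc + orr); c_src <- (1L + oc):(Wc + oc)
      rok <- r_src >= 1L & r_src <= nrs; cok <- c_src >= 1L & c_src <= ncs
      res[which(rok), which(cok)] <- m[r_src[rok], c_src[cok], drop = FALSE]
      return(res)
    }
    res <- matrix(nd, Hc, Wc)
    for (r0 in seq(0L, Hc - 1L, by = chunk_rows)) {
      r1 <- min(Hc - 1L, r0 + chunk_rows - 1L)
      rr <- r0:r1
      u <- matrix(rep(seq_len(Wc) - 0.5, each = length(rr)),
                  nrow = length(rr))
      v <- matrix(rep(rr + 0.5, times = Wc), nrow = length(rr))
      sp <- apply_homography(H, u, v)
      if (resample == "nearest") {
        ci <- floor(sp$x) + 1L; ri <- floor(sp$y) + 1L
        ok <- ci >= 1L & ci <= ncs & ri >= 1L & ri <= nrs
        vals <- matrix(nd, length(rr), Wc)
        vals[ok] <- m[cbind(ri[ok], ci[ok])]
      } else {
        cf <- sp$x - 0.5; rf <- sp$y - 0.5   # centre-based continuous
        c0 <- floor(cf); r0f <- floor(rf)
        fx <- cf - c0; fy <- rf - r0f
        gv <- function(ri, ci) {
          ok <- ci >= 0L & ci <= ncs - 1L & ri >= 0L & ri <= nrs - 1L
          z <- matrix(NA_real_, nrow(ri), ncol(ri))
          z[ok] <- m[cbind(ri[ok] + 1L, ci[ok] + 1L)]
          z
        }
        v00 <- gv(r0f, c0); v01 <- gv(r0f, c0 + 1)
        v10 <- gv(r0f + 1, c0); v11 <- gv(r0f + 1, c0 + 1)
        vals <- (1 - fy) * ((1 - fx) * v00 + fx * v01) +
          fy * ((1 - fx) * v10 + fx * v11)
        vals[is.na(vals)] <- nd
      }
      res[rr + 1L, ] <- vals
    }
    res
  })

  rect <- mb_raster(out_bands, x0 = minx, y0 = maxy, gsd = gsd,
                    crs = raster$crs, nodata = nd,
                    wavelengths = raster$wavelengths)
  Hinv <- solve(H)
  list(
    raster = rect,
    H = H,
    to_source = function(col, row) apply_homography(H, col, row),
    to_rectified = function(col, row) apply_homography(Hinv, col, row)
  )
}
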