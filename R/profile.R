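# 1-D projection profiles and grayscale morphology.
#
# Block and row boundaries are found on projection profiles: the sum of
# image pixel values along one axis. Profiles are smoothed by a grayscale
# opening with a flat line structuring element (SE), then eroded with a
# shorter SE (which deliberately widens every trough, under-estimating the
# extent of the vegetated regions between them), and regional minima of the
# result mark the soil troughs between blocks or rows.

#' Projection profile of an image region
#'
#' @param image numeric matrix (rows = image rows).
#' @param axis `"x"` sums along x (row sums; vertical profile over image
#'   rows), `"y"` sums along y (column sums; horizontal profile over image
#'   columns).
#' @return numeric vector of sums; `NA` pixels count as 0.
#' @export
project <- function(image, axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (length(image) == 0L) stop("empty image region", call. = FALSE)
  image[is.na(image)] <- 0
  if (axis == "x") rowSums(image) else colSums(image)
}

# flat-line erosion (min filter); border padded with +Inf
erode1d <- function(x, len) {
  if (len <= 1L) return(x)
  h <- (len - 1L) %/% 2L
  n <- length(x)
  out <- x
  for (d in seq_len(h)) {
    out <- pmin(out,
                c(x[(d + 1L):n], rep(Inf, d)),
                c(rep(Inf, d), x[1L:(n - d)]))
  }
  out
}

# flat-line dilation (max filter); border padded with -Inf
dilate1d <- function(x, len) {
  if (len <= 1L) return(x)
  h <- (len - 1L) %/% 2L
  n <- length(x)
  out <- x
  for (d in seq_len(h)) {
    out <- pmax(out,
                c(x[(d + 1L):n], rep(-Inf, d)),
                c(rep(-Inf, d), x[1L:(n - d)]))
  }
  out
}

#' Grayscale opening with a flat line SE
#' @param x numeric vector.
#' @param len SE length (odd).
#' @return opened vector.
#' @export
open1d <- function(x, len) dilate1d(erode1d(x, len), len)

# SE lengths are centred and forced odd (even lengths rounded up so the
# window always covers the half-length it nominally represents)
se_length <- function(feature_length, divisor) {
  len <- max(1L, as.integer(feature_length) %/% as.integer(divisor))
  if (len %% 2L == 0L) len + 1L else len
}

#' Regional minima of a vector
#'
#' A regional minimum is a maximal run of equal values strictly lower than
#' both neighbouring values; the vector borders count as +Inf neighbours, so
#' a low plateau touching a border qualifies.
#'
#' @param x numeric vector.
#' @return tibble with 1-based `left`, `right` run edges, `center` (lower
#'   median of the run) and the run `value`.
#' @export
regional_minima <- function(x) {
  n <- length(x)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  lv <- c(Inf, r$values[-length(r$values)])
  rv <- c(r$values[-1L], Inf)
  keep <- r$values < lv & r$values < rv
  # a run spanning the whole profile is the image, not a trough
  keep <- keep & !(starts == 1L & ends == n)
  tibble::tibble(
    left = starts[keep],
    right = ends[keep],
    center = (starts[keep] + ends[keep]) %/% 2L,
    value = r$values[keep]
  )
}

#' Process a projection profile into a trough set
#'
#' Opening with a flat line SE of length `feature_length %/% 2`, erosion
#' with one of length `feature_length %/% 3` (even lengths rounded up to
#' odd), then regional minima. The only external parameter is the expected
#' feature length in pixels: the plant-row length when separating blocks,
#' the expected plant width when separating rows.
#'
#' @param values numeric profile.
#' @param feature_length expected feature length, pixels (>= 6).
#' @return tibble of troughs as in [regional_minima()].
#' @export
process_profile <- function(values, feature_length) {
  if (feature_length < 6) {
    stop("feature_length must be >= 6 so both structuring elements are >= 2",
         call. = FALSE)
  }
  se1 <- se_length(feature_length, 2L)
  se2 <- se_length(feature_length, 3L)
  if (length(values) < max(se1, se2)) {
    stop("profile shorter than the structuring element", call. = FALSE)
  }
  regional_minima(erode1d(open1d(values, se1), se2))
}
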