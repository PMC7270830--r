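# Box growing: recover the deliberately under-estimated vertical extent of
# plant-row boxes by absorbing, from both ends of the gap between two
# vertically linked boxes, the profile rows that carry more mass than bare
# background, until only background-level mass remains in the middle.

#' Grow two linked row boxes across the gap between them
#'
#' `f` is the projection profile of the link region (row-wise pixel sums),
#' `f[1]` along the bottom edge of the top box and `f[n]` along the top edge
#' of the bottom box. Two pointers walk inwards from both ends; at each step
#' the heavier end row is absorbed (both on a tie) and the loop stops when
#' the unabsorbed mass `s - a` falls below the scaled background threshold
#' `t1`. The `"printed"` variant scales the threshold by `n - j + 1` rows;
#' the default `"prose"` variant scales by the rows actually remaining
#' between the growing edges, `k - j + 1`, which keeps absorbing while any
#' above-background mass remains between the boxes (see the methods
#' vignette for why this is the default).
#'
#' @param f numeric profile over the gap rows (length `n >= 1`).
#' @param t background threshold: mean background (non-plant) pixel
#'   intensity, must be > 0.
#' @param width link-region width in pixels.
#' @param variant `"prose"` (default) or `"printed"` threshold scaling.
#' @return integer vector `c(top = j - 1, bottom = n - k)`: pixel rows to
#'   add to the bottom edge of the top box and to the top edge of the
#'   bottom box. Always satisfies `top + bottom <= n`.
#' @export
grow_boxes <- function(f, t, width, variant = c("prose", "printed")) {
  variant <- match.arg(variant)
  if (t <= 0) stop("background threshold t must be > 0", call. = FALSE)
  if (width < 1) stop("link width must be >= 1", call. = FALSE)
  n <- length(f)
  if (n < 1L) stop("empty link profile", call. = FALSE)
  j <- 1L; k <- n; a <- 0
  s <- sum(f)
  while (j < k) {
    if (f[j] > f[k]) {
      a <- a + f[j]; j <- j + 1L
    } else if (f[j] == f[k]) {
      a <- a + f[j] + f[k]; j <- j + 1L; k <- k - 1L
    } else {
      a <- a + f[k]; k <- k - 1L
    }
    rows <- if (variant == "printed") n - j + 1L else k - j + 1L
    if (s - a <= t * width * max(rows, 0L)) break
  }
  c(top = j - 1L, bottom = n - k)
}
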