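# Individual plant-centre detection by normalized cross-correlation
# template matching. The matching score is zero-normalized cross-correlation
# (ZNCC), which is invariant to local brightness scale and offset; flat
# (zero-variance) windows score 0.

# cumulative-sum integral image with a zero top row / left column
.sat <- function(m) {
  s <- apply(m, 2L, cumsum)
  s <- t(apply(s, 1L, cumsum))
  rbind(0, cbind(0, s))
}

# sums of all kr x kc windows of m (result dim: (nr-kr+1) x (nc-kc+1))
.box_sums <- function(m, kr, kc) {
  s <- .sat(m)
  nr <- nrow(m); nc <- ncol(m)
  ri <- 1L:(nr - kr + 1L); ci <- 1L:(nc - kc + 1L)
  s[ri + kr, ci + kc, drop = FALSE] - s[ri, ci + kc, drop = FALSE] -
    s[ri + kr, ci, drop = FALSE] + s[ri, ci, drop = FALSE]
}

# valid cross-correlation of image with kernel via FFT
.xcorr_valid <- function(img, ker) {
  nr <- nrow(img); nc <- ncol(img)
  kr <- nrow(ker); kc <- ncol(ker)
  pr <- stats::nextn(nr + kr - 1L, c(2, 3, 5))
  pc <- stats::nextn(nc + kc - 1L, c(2, 3, 5))
  ip <- matrix(0, pr, pc); ip[1:nr, 1:nc] <- img
  kp <- matrix(0, pr, pc)
  kp[1:kr, 1:kc] <- ker[kr:1, kc:1, drop = FALSE]   # rotate 180 -> correlation
  fullc <- Re(stats::fft(stats::fft(ip) * stats::fft(kp), inverse = TRUE)) /
    (pr * pc)
  fullc[kr:nr, kc:nc, drop = FALSE]
}

#' Build a plant template from sample windows
#'
#' The template is the pixel-wise mean of the samples; the reported sample
#' correlation is the mean Pearson correlation between the template and
#' each sample. Samples are windows of `width x height` pixels extended by
#' a `context` margin on every side (the effective matched window is
#' `(width + 2 context) x (height + 2 context)`).
#'
#' @param image NDVI matrix to cut sample windows from (used with
#'   `centers`).
#' @param centers tibble with 0-based pixel columns `col`, `row` of sample
#'   plant centres.
#' @param windows alternatively, a list of equally sized sample matrices.
#' @param width,height sample window size, pixels.
#' @param context extra margin appended around each sample, pixels; set 0
#'   to disable.
#' @param threshold,tolerance stored matching parameters (minimum score;
#'   merge distance in pixels).
#' @return list of class `plant_template`.
#' @export
build_template <- function(image = NULL, centers = NULL, windows = NULL,
                           width = 20, height = 20, context = 4,
                           threshold = 0.6, tolerance = 3) {
  if (is.null(windows)) {
    stopifnot(!is.null(image), !is.null(centers))
    we <- width + 2L * context; he <- height + 2L * context
    hc <- (we - 1L) %/% 2L; hr <- (he - 1L) %/% 2L
    windows <- lapply(seq_len(nrow(centers)), function(i) {
      c0 <- centers$col[i] - hc; r0 <- centers$row[i] - hr
      if (c0 < 0L || r0 < 0L || c0 + we > ncol(image) || r0 + he > nrow(image)) {
        stop("sample window extends outside the image", call. = FALSE)
      }
      image[(r0 + 1L):(r0 + he), (c0 + 1L):(c0 + we), drop = FALSE]
    })
  }
  if (length(windows) < 2L) stop("need >= 2 sample windows", call. = FALSE)
  dims <- unique(lapply(windows, dim))
  if (length(dims) != 1L) {
    stop("sample windows have inconsistent sizes", call. = FALSE)
  }
  tmpl <- Reduce(`+`, windows) / length(windows)
  cors <- vapply(windows, function(w) {
    if (sd(w) == 0 || sd(tmpl) == 0) return(1)
    stats::cor(as.numeric(tmpl), as.numeric(w))
  }, numeric(1))
  structure(list(template = tmpl, width = width, height = height,
                 context = context, n_samples = length(windows),
                 correlation = mean(cors), threshold = threshold,
                 tolerance = tolerance),
            class = "plant_template")
}

#' @export
print.plant_template <- function(x, ...) {
  cat(sprintf(paste0("<plant_template> %d x %d px (%d samples, context %d),",
                     " sample correlation %.3f\n"),
              nrow(x$template), ncol(x$template), x$n_samples, x$context,
              x$correlation))
  invisible(x)
}

#' Match a plant template across an image
#'
#' Computes the ZNCC score at every valid window position, keeps local
#' maxima with score >= the threshold, and merges detections closer than
#' the tolerance by non-maximum suppression (higher score wins; ties go to
#' the smaller `(row, col)`).
#'
#' @param image NDVI matrix.
#' @param model a `plant_template`.
#' @param region optional 0-based half-open search rectangle (list or row
#'   with `x0`, `x1`, `y0`, `y1`).
#' @param threshold,tolerance overrides of the model's stored values.
#' @return tibble of candidate centres: 0-based `col`, `row`, `score`.
#' @export
match_template <- function(image, model, region = NULL,
                           threshold = model$threshold,
                           tolerance = model$tolerance) {
  off_c <- 0L; off_r <- 0L
  if (!is.null(region)) {
    image <- image[(region$y0 + 1L):region$y1,
                   (region$x0 + 1L):region$x1, drop = FALSE]
    off_c <- as.integer(region$x0); off_r <- as.integer(region$y0)
  }
  tmpl <- model$template
  kr <- nrow(tmpl); kc <- ncol(tmpl)
  if (nrow(image) < kr || ncol(image) < kc) {
    stop("search region smaller than the template window", call. = FALSE)
  }
  image[is.na(image)] <- 0
  t0 <- tmpl - mean(tmpl)
  denom_t <- sqrt(sum(t0^2))
  n <- kr * kc
  num <- .xcorr_valid(image, t0)
  s1 <- .box_sums(image, kr, kc)
  s2 <- .box_sums(image^2, kr, kc)
  varw <- s2 - s1^2 / n
  varw[varw < n * 1e-10] <- NA
  score <- num / (sqrt(varw) * max(denom_t, 1e-12))
  score[is.na(score)] <- 0

  # strict over earlier (row-major) neighbours, >= over later ones, so one
  # point per tied plateau survives, the smallest (row, col)
  nr <- nrow(score); nc <- ncol(score)
  pad <- function(m, dr, dc, fill) {
    out <- matrix(fill, nr, nc)
    rs <- max(1L, 1L + dr):min(nr, nr + dr)
    cs <- max(1L, 1L + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
    out
  }
  ismax <- score > pad(score, 1L, 1L, -Inf) &   # vs up-left
    score > pad(score, 1L, 0L, -Inf) &          # vs up
    score > pad(score, 1L, -1L, -Inf) &         # vs up-right
    score > pad(score, 0L, 1L, -Inf) &          # vs left
    score >= pad(score, 0L, -1L, -Inf) &
    score >= pad(score, -1L, 1L, -Inf) &
    score >= pad(score, -1L, 0L, -Inf) &
    score >= pad(score, -1L, -1L, -Inf) &
    score >= threshold
  idx <- which(ismax)
  if (!length(idx)) {
    return(tibble::tibble(col = integer(), row = integer(),
                          score = numeric()))
  }
  ri <- (idx - 1L) %% nr + 1L
  ci <- (idx - 1L) %/% nr + 1L
  cand <- tibble::tibble(
    col = ci - 1L + (kc - 1L) %/% 2L + off_c,
    row = ri - 1L + (kr - 1L) %/% 2L + off_r,
    score = score[idx]
  ) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$row, .data$col)

  # greedy non-maximum suppression on a coarse grid
  keep <- logical(nrow(cand))
  cell <- ceiling(tolerance)
  seen <- new.env(hash = TRUE)
  for (i in seq_len(nrow(cand))) {
    gx <- cand$col[i] %/% cell; gy <- cand$row[i] %/% cell
    ok <- TRUE
    for (dx in -1:1) for (dy in -1:1) {
      key <- paste(gx + dx, gy + dy)
      prev <- seen[[key]]
      if (!is.null(prev)) {
        d2 <- (cand$col[prev] - cand$col[i])^2 + (cand$row[prev] - cand$row[i])^2
        if (any(d2 < tolerance^2)) { ok <- FALSE; break }
      }
    }
    if (ok) {
      keep[i] <- TRUE
      key <- paste(gx, gy)
      seen[[key]] <- c(seen[[key]], i)
    }
  }
  cand[keep, ] |> dplyr::arrange(.data$row, .data$col)
}

#' Rebuild a template from accepted detection centres
#'
#' One refinement pass: the windows around the accepted centres (all
#' detected plants, spanning the full range of plant sizes) become the new
#' sample set and the template is rebuilt as their mean. Centres whose
#' window would leave the image are skipped. A single rebuild typically
#' lifts weak plants crowded by strong neighbours above the match
#' threshold.
#'
#' @param image NDVI matrix.
#' @param model the current `plant_template`.
#' @param centers tibble of accepted centres (0-based `col`, `row`).
#' @return a new `plant_template` with the same matching parameters.
#' @export
refine_template <- function(image, model, centers) {
  we <- ncol(model$template); he <- nrow(model$template)
  hc <- (we - 1L) %/% 2L; hr <- (he - 1L) %/% 2L
  ok <- centers$col >= hc & centers$row >= hr &
    centers$col + (we - hc) <= ncol(image) &
    centers$row + (he - hr) <= nrow(image)
  cen <- centers[ok, , drop = FALSE]
  if (nrow(cen) < 2L) return(model)
  get_win <- function(i) {
    c0 <- cen$col[i] - hc; r0 <- cen$row[i] - hr
    image[(r0 + 1L):(r0 + he), (c0 + 1L):(c0 + we), drop = FALSE]
  }
  acc <- matrix(0, he, we)
  for (i in seq_len(nrow(cen))) acc <- acc + get_win(i)
  tmpl <- acc / nrow(cen)
  tv <- as.numeric(tmpl)
  cors <- vapply(seq_len(nrow(cen)), function(i) {
    w <- as.numeric(get_win(i))
    if (sd(w) == 0) 1 else stats::cor(tv, w)
  }, numeric(1))
  structure(list(template = tmpl, width = model$width,
                 height = model$height, context = model$context,
                 n_samples = nrow(cen), correlation = mean(cors),
                 threshold = model$threshold, tolerance = model$tolerance),
            class = "plant_template")
}

#' Automatically pick template sample centres from detected row boxes
#'
#' Deterministic stand-in for interactive sample picking: takes `n` row
#' boxes spread evenly across the box set and uses each box's brightest
#' NDVI pixel as a sample centre, skipping boxes whose window would fall
#' outside the image.
#'
#' @param image NDVI matrix.
#' @param boxes row-box tibble.
#' @param n number of samples.
#' @param window_half half-size of the sample window, pixels.
#' @return tibble of 0-based `col`, `row` sample centres.
#' @export
pick_template_samples <- function(image, boxes, n = 35, window_half = 14) {
  take <- unique(round(seq(1, nrow(boxes), length.out = min(n, nrow(boxes)))))
  out <- purrr::map_dfr(take, function(i) {
    b <- boxes[i, ]
    sub <- image[(b$y0 + 1L):b$y1, (b$x0 + 1L):b$x1, drop = FALSE]
    ij <- arrayInd(which.max(sub), dim(sub))
    tibble::tibble(col = b$x0 + ij[2L] - 1L, row = b$y0 + ij[1L] - 1L)
  }) |>
    dplyr::filter(.data$col >= window_half, .data$row >= window_half,
                  .data$col < ncol(image) - window_half,
                  .data$row < nrow(image) - window_half)
  out
}
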