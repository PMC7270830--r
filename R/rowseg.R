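# Block / row segmentation from projection profiles, initial row boxes and
# linking + growing across the inter-box gaps.

#' Segmentation parameters
#'
#' @param expected_row_length expected plant-row length, pixels (the single
#'   external parameter of block detection).
#' @param expected_plant_width expected plant width/diameter, pixels (used
#'   for row detection within a block).
#' @param background_t background threshold for box growing; `NULL` =
#'   estimate from the image as the mean intensity outside all initial
#'   boxes.
#' @param min_band_frac bands shorter than this fraction of
#'   `expected_row_length` are discarded as soil-margin slivers.
#' @param expected_blocks optional expected number of blocks (warning when
#'   detection disagrees).
#' @return list of class `seg_params`.
#' @export
seg_params <- function(expected_row_length, expected_plant_width,
                       background_t = NULL, min_band_frac = 0.5,
                       expected_blocks = NULL) {
  stopifnot(expected_row_length > 0, expected_plant_width > 0)
  structure(list(expected_row_length = expected_row_length,
                 expected_plant_width = expected_plant_width,
                 background_t = background_t,
                 min_band_frac = min_band_frac,
                 expected_blocks = expected_blocks),
            class = "seg_params")
}

# NDVI can be negative; profiles assume non-negative mass, so shift the
# image up by its (negative) minimum before projecting. The shift is
# returned so callers can report it.
ndvi_shift <- function(image) {
  mn <- suppressWarnings(min(image, na.rm = TRUE))
  if (is.finite(mn) && mn < 0) -mn else 0
}

#' Detect plant blocks as horizontal bands of a rectified NDVI image
#'
#' The vertical projection profile (sums along x) is processed with
#' `expected_row_length` as the feature length; trough centres become
#' horizontal dividing lines, and blocks are the intervals between
#' consecutive dividing lines and the image borders. Bands too short to
#' hold a plant row (soil margins between a border trough and the first
#' alley trough) are discarded.
#'
#' @param image rectified NDVI matrix.
#' @param params a [seg_params].
#' @return list with `bands` (tibble of 0-based half-open pixel rows
#'   `y0`/`y1` and tight trough-edge bounds `y0e`/`y1e`), `troughs`, and
#'   the non-negativity `shift` applied.
#' @export
detect_blocks <- function(image, params) {
  shift <- ndvi_shift(image)
  f <- project(image + shift, "x")
  troughs <- process_profile(f, params$expected_row_length)
  n <- length(f)
  if (nrow(troughs) == 0L) {
    if (!is.null(params$expected_blocks) && params$expected_blocks > 1) {
      warning("no dividing troughs found; returning a single block",
              call. = FALSE)
    }
    bands <- tibble::tibble(y0 = 0L, y1 = n, y0e = 0L, y1e = n)
  } else {
    cuts0 <- troughs$center - 1L            # 0-based dividing lines
    lo <- c(0L, cuts0)
    hi <- c(cuts0, n)
    # tight bounds: from the lower edge of the trough above to the upper
    # edge of the trough below (the deliberate under-estimate)
    lo_e <- c(0L, troughs$right)            # right edge is 1-based run end
    hi_e <- c(troughs$left - 1L, n)
    bands <- tibble::tibble(y0 = lo, y1 = hi, y0e = pmin(lo_e, hi),
                            y1e = pmax(hi_e, lo))
  }
  keep <- (bands$y1 - bands$y0) >= params$min_band_frac * params$expected_row_length
  if (any(!keep)) {
    message(sum(!keep), " margin sliver band(s) discarded")
  }
  bands <- bands[keep, , drop = FALSE]
  bands$block <- seq_len(nrow(bands))
  if (!is.null(params$expected_blocks) &&
      nrow(bands) != params$expected_blocks) {
    warning(sprintf("detected %d blocks but %d expected", nrow(bands),
                    params$expected_blocks), call. = FALSE)
  }
  list(bands = bands, troughs = troughs, shift = shift)
}

#' Detect plant rows within one block band
#'
#' Same profile processing as block detection, applied to the horizontal
#' projection (sums along y) of the band, with the expected plant width as
#' the feature length. Rows are the intervals between consecutive trough
#' centres.
#'
#' @param image rectified NDVI matrix.
#' @param band one row of the `bands` tibble from [detect_blocks()].
#' @param params a [seg_params].
#' @return tibble of 0-based half-open column ranges `x0`/`x1`, one per row.
#' @export
detect_rows <- function(image, band, params) {
  shift <- ndvi_shift(image)
  sub <- image[(band$y0 + 1L):band$y1, , drop = FALSE]
  f <- project(sub + shift, "y")
  troughs <- process_profile(f, params$expected_plant_width)
  if (nrow(troughs) < 2L) {
    warning("no plant rows found in band (soil-only?)", call. = FALSE)
    return(tibble::tibble(x0 = integer(), x1 = integer()))
  }
  cuts0 <- troughs$center - 1L
  tibble::tibble(x0 = cuts0[-length(cuts0)], x1 = cuts0[-1L])
}

#' Build initial plant-row boxes from detected blocks and rows
#'
#' One box per (block, row): the horizontal extent is the row interval, the
#' vertical extent the block's tight trough-edge bounds, which deliberately
#' under-estimate the rows' true vertical extent (to be recovered by
#' [link_and_grow()]).
#'
#' @param blocks result of [detect_blocks()].
#' @param rows_by_block list of [detect_rows()] results, one per band.
#' @return tibble of row boxes (0-based half-open `x0`,`x1`,`y0`,`y1`).
#' @export
initial_row_boxes <- function(blocks, rows_by_block) {
  bands <- blocks$bands
  out <- purrr::map_dfr(seq_len(nrow(bands)), function(i) {
    rows <- rows_by_block[[i]]
    if (nrow(rows) == 0L) return(NULL)
    tibble::tibble(
      block = bands$block[i],
      row_in_block = seq_len(nrow(rows)),
      x0 = rows$x0, x1 = rows$x1,
      y0 = bands$y0e[i], y1 = bands$y1e[i]
    )
  })
  out$box_id <- sprintf("B%02d-W%03d", out$block, out$row_in_block)
  out$grown_top <- 0L
  out$grown_bottom <- 0L
  out
}

#' Link vertically adjacent row boxes and grow them across the gaps
#'
#' Boxes in vertically adjacent blocks that share x-overlap are linked (at
#' most one link above and one below per box). Each link's rectangle spans
#' the gap rows between the two boxes and the intersection of their column
#' ranges; its row-wise profile is handed to [grow_boxes()] and the box
#' edges are extended by the returned row counts. Boxes on the field
#' boundary are additionally grown toward the image border through a
#' virtual border link (rows assigned to the border side are discarded), so
#' plants overhanging the outer box edges are recovered too.
#'
#' @param boxes tibble from [initial_row_boxes()].
#' @param image rectified NDVI matrix.
#' @param t background threshold; `NULL` = mean intensity outside all
#'   initial boxes (after the non-negativity shift).
#' @param variant threshold scaling passed to [grow_boxes()].
#' @param border_links grow boundary boxes toward the image borders.
#' @return `boxes` with updated `y0`/`y1` and `grown_top`/`grown_bottom`.
#' @export
link_and_grow <- function(boxes, image, t = NULL,
                          variant = c("prose", "printed"),
                          border_links = TRUE) {
  variant <- match.arg(variant)
  shift <- ndvi_shift(image)
  img <- image + shift
  img[is.na(img)] <- 0
  H <- nrow(img); W <- ncol(img)
  if (is.null(t)) {
    mask <- matrix(TRUE, H, W)
    for (i in seq_len(nrow(boxes))) {
      mask[(boxes$y0[i] + 1L):boxes$y1[i],
           (boxes$x0[i] + 1L):boxes$x1[i]] <- FALSE
    }
    # median, not mean: the region outside the initial boxes contains the
    # plant overhangs growing is meant to recover, which would inflate a
    # mean; the median of a soil-dominated region estimates the background
    t <- median(img[mask])
    if (!is.finite(t) || t <= 0) t <- mean(img) * 0.5
  }

  link_profile <- function(yl0, yl1, xl0, xl1) {
    # 0-based half-open -> 1-based inclusive matrix indices
    rowSums(img[(yl0 + 1L):yl1, (xl0 + 1L):xl1, drop = FALSE])
  }

  blocks <- sort(unique(boxes$block))
  for (bi in seq_along(blocks)[-1L]) {
    up <- which(boxes$block == blocks[bi - 1L])
    dn <- which(boxes$block == blocks[bi])
    used_dn <- rep(FALSE, length(dn))
    for (u in up) {
      ov <- pmin(boxes$x1[dn], boxes$x1[u]) - pmax(boxes$x0[dn], boxes$x0[u])
      cand <- which(ov > 0 & !used_dn)
      if (!length(cand)) next
      d <- dn[cand[which.max(ov[cand])]]
      used_dn[cand[which.max(ov[cand])]] <- TRUE
      xl0 <- max(boxes$x0[u], boxes$x0[d])
      xl1 <- min(boxes$x1[u], boxes$x1[d])
      yl0 <- boxes$y1[u]; yl1 <- boxes$y0[d]
      if (yl1 <= yl0) next
      f <- link_profile(yl0, yl1, xl0, xl1)
      gb <- grow_boxes(f, t, xl1 - xl0, variant)
      boxes$y1[u] <- boxes$y1[u] + gb[["top"]]
      boxes$grown_bottom[u] <- boxes$grown_bottom[u] + gb[["top"]]
      boxes$y0[d] <- boxes$y0[d] - gb[["bottom"]]
      boxes$grown_top[d] <- boxes$grown_top[d] + gb[["bottom"]]
    }
  }

  if (border_links) {
    first_b <- which(boxes$block == blocks[1L])
    last_b <- which(boxes$block == blocks[length(blocks)])
    for (i in first_b) {
      if (boxes$y0[i] > 0L) {
        f <- link_profile(0L, boxes$y0[i], boxes$x0[i], boxes$x1[i])
        gb <- grow_boxes(f, t, boxes$x1[i] - boxes$x0[i], variant)
        boxes$y0[i] <- boxes$y0[i] - gb[["bottom"]]
        boxes$grown_top[i] <- boxes$grown_top[i] + gb[["bottom"]]
      }
    }
    for (i in last_b) {
      if (boxes$y1[i] < H) {
        f <- link_profile(boxes$y1[i], H, boxes$x0[i], boxes$x1[i])
        gb <- grow_boxes(f, t, boxes$x1[i] - boxes$x0[i], variant)
        boxes$y1[i] <- boxes$y1[i] + gb[["top"]]
        boxes$grown_bottom[i] <- boxes$grown_bottom[i] + gb[["top"]]
      }
    }
  }
  attr(boxes, "background_t") <- t
  boxes
}

#' Choose the consensus polygon set across time points
#'
#' Given candidate row-polygon sets detected on different imaging dates,
#' returns the set whose polygon-area sample variance is smallest (ties:
#' earliest time point), with a per-set variance report.
#'
#' @param sets named list of row-box tibbles (names = time point labels, in
#'   chronological order).
#' @return list with `chosen` (the winning tibble), `label`, and `report`
#'   (tibble of time point, n_polygons, area_variance).
#' @export
select_consensus <- function(sets) {
  if (length(sets) == 0L) stop("no candidate polygon sets", call. = FALSE)
  if (is.null(names(sets))) names(sets) <- sprintf("t%02d", seq_along(sets))
  report <- purrr::imap_dfr(sets, function(s, nm) {
    areas <- (s$x1 - s$x0) * (s$y1 - s$y0)
    tibble::tibble(time_point = nm, n_polygons = nrow(s),
                   area_variance = if (length(areas) > 1) var(areas) else 0)
  })
  if (length(unique(report$n_polygons)) > 1L) {
    message("candidate sets differ in polygon count: ",
            paste(report$n_polygons, collapse = ", "))
  }
  best <- which.min(report$area_variance)   # which.min takes the first tie
  list(chosen = sets[[best]], label = names(sets)[best], report = report)
}
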