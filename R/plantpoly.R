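# Assignment of detected centres to row boxes, file-driven quality control,
# and splitting each row box into per-plant polygons.

#' Assign candidate centres to row boxes and apply QC edits
#'
#' Candidates outside every row box are discarded. An optional edits table
#' (columns `action` in add/remove, `col`, `row`, 0-based pixels) is then
#' applied deterministically: `add` inserts a manual centre (it must land
#' inside the image, and is discarded with the same rule if outside all
#' boxes); `remove` deletes the nearest kept detection within the
#' tolerance.
#'
#' @param candidates tibble from [match_template()].
#' @param boxes row-box tibble (after growing).
#' @param edits optional edits tibble or CSV path.
#' @param image_dim `c(nrow, ncol)` of the image, for edit validation.
#' @param tolerance match distance for `remove` edits, pixels.
#' @return tibble of kept centres with `box_id`, `provenance`
#'   (matched/manual-add) and `status` (kept).
#' @export
filter_and_qc <- function(candidates, boxes, edits = NULL, image_dim = NULL,
                          tolerance = 3) {
  assign_box <- function(col, row) {
    # boxes are pairwise disjoint; order candidates by column for fast lookup
    out <- rep(NA_character_, length(col))
    for (i in seq_len(nrow(boxes))) {
      inside <- col >= boxes$x0[i] & col < boxes$x1[i] &
        row >= boxes$y0[i] & row < boxes$y1[i]
      out[inside] <- boxes$box_id[i]
    }
    out
  }
  kept <- candidates
  kept$box_id <- assign_box(kept$col, kept$row)
  n_out <- sum(is.na(kept$box_id))
  if (n_out > 0) message(n_out, " candidate(s) outside all row boxes discarded")
  kept <- kept[!is.na(kept$box_id), , drop = FALSE]
  kept$provenance <- rep("matched", nrow(kept))

  if (!is.null(edits)) {
    if (is.character(edits)) {
      edits <- tibble::as_tibble(read.csv(edits, stringsAsFactors = FALSE))
    }
    for (i in seq_len(nrow(edits))) {
      e <- edits[i, ]
      if (!is.null(image_dim) &&
          (e$col < 0 || e$row < 0 || e$col >= image_dim[2] ||
           e$row >= image_dim[1])) {
        stop(sprintf("edit row %d references pixel (%s, %s) outside the image",
                     i, format(e$col), format(e$row)), call. = FALSE)
      }
      if (e$action == "add") {
        bid <- assign_box(e$col, e$row)
        if (is.na(bid)) {
          message(sprintf("manual add at (%d, %d) lies outside all boxes; discarded",
                          e$col, e$row))
        } else {
          kept <- dplyr::bind_rows(kept, tibble::tibble(
            col = as.integer(e$col), row = as.integer(e$row),
            score = NA_real_, box_id = bid, provenance = "manual-add"))
        }
      } else if (e$action == "remove") {
        d2 <- (kept$col - e$col)^2 + (kept$row - e$row)^2
        hit <- which(d2 <= tolerance^2)
        if (length(hit)) {
          kept <- kept[-hit[which.min(d2[hit])], , drop = FALSE]
        } else {
          warning(sprintf("remove edit at (%d, %d) matches no detection",
                          e$col, e$row), call. = FALSE)
        }
      } else {
        stop("unknown edit action '", e$action, "' (use add/remove)",
             call. = FALSE)
      }
    }
  }
  kept$status <- rep("kept", nrow(kept))
  dplyr::arrange(kept, .data$box_id, .data$row, .data$col)
}

#' Split a row box into per-plant polygons at centre midpoints
#'
#' Centres are sorted along the row axis; cut lines perpendicular to the
#' row axis are placed at the midpoints between consecutive centres, with
#' the first and last polygons extending to the box ends. The polygons
#' partition the box exactly and each contains its centre.
#'
#' @param box one row of a row-box tibble.
#' @param centers tibble of centres inside the box (0-based `col`, `row`).
#' @param axis row axis: `"y"` (rows run vertically), `"x"`, or `NULL` to
#'   pick the box's long axis.
#' @return tibble of plant rectangles with `position` along the row.
#' @export
split_row_polygon <- function(box, centers, axis = NULL) {
  if (nrow(centers) == 0L) {
    return(tibble::tibble(position = integer(), x0 = integer(),
                          x1 = integer(), y0 = integer(), y1 = integer(),
                          col = integer(), row = integer()))
  }
  if (is.null(axis)) {
    axis <- if ((box$y1 - box$y0) >= (box$x1 - box$x0)) "y" else "x"
  }
  u <- if (axis == "y") centers$row else centers$col
  ord <- order(u, centers$col, centers$row)
  centers <- centers[ord, , drop = FALSE]
  u <- u[ord]
  lo <- if (axis == "y") box$y0 else box$x0
  hi <- if (axis == "y") box$y1 else box$x1
  cuts <- if (length(u) > 1L) (u[-length(u)] + u[-1L] + 1L) %/% 2L else integer()
  b0 <- c(lo, cuts)
  b1 <- c(cuts, hi)
  out <- tibble::tibble(position = seq_along(u), col = centers$col,
                        row = centers$row)
  if (axis == "y") {
    out$x0 <- box$x0; out$x1 <- box$x1; out$y0 <- b0; out$y1 <- b1
  } else {
    out$y0 <- box$y0; out$y1 <- box$y1; out$x0 <- b0; out$x1 <- b1
  }
  out
}

#' Split every row box into identified plant polygons
#'
#' Applies [split_row_polygon()] per box and assigns compound plant IDs
#' `B<block>-P<plot>-R<row-in-plot>-N<position>` from the box's block and
#' row-in-block indices. Boxes containing no centres are flagged and yield
#' no polygons.
#'
#' @param boxes row-box tibble.
#' @param centers kept centres from [filter_and_qc()] (with `box_id`).
#' @param rows_per_plot rows per plot, to map row-in-block to plot and
#'   row-in-plot indices.
#' @param axis passed to [split_row_polygon()].
#' @return tibble of plant polygons; empty boxes are reported in the
#'   `empty_boxes` attribute.
#' @export
split_row_polygons <- function(boxes, centers, rows_per_plot = 3,
                               axis = NULL) {
  by_box <- split(centers, centers$box_id)
  out <- purrr::map_dfr(seq_len(nrow(boxes)), function(i) {
    b <- boxes[i, ]
    cs <- by_box[[b$box_id]]
    if (is.null(cs) || nrow(cs) == 0L) return(NULL)
    polys <- split_row_polygon(b, cs, axis = axis)
    plot_index <- (b$row_in_block - 1L) %/% rows_per_plot + 1L
    row_in_plot <- (b$row_in_block - 1L) %% rows_per_plot + 1L
    polys$box_id <- b$box_id
    polys$block <- b$block
    polys$plot_index <- plot_index
    polys$row_in_plot <- row_in_plot
    polys$plot_id <- sprintf("B%02d-P%02d", b$block, plot_index)
    polys$plant_id <- sprintf("B%02d-P%02d-R%d-N%02d", b$block, plot_index,
                              row_in_plot, polys$position)
    polys
  })
  empty <- setdiff(boxes$box_id, unique(centers$box_id))
  if (length(empty)) {
    message(length(empty), " row box(es) contain no centres (flagged)")
  }
  attr(out, "empty_boxes") <- empty
  out
}
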