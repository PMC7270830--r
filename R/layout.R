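#' Define a spaced-plant trial layout
#'
#' Describes a randomized-complete-block spaced-plant trial: `n_entries`
#' entries replicated once per block (`n_reps` blocks), each plot holding
#' `rows_per_plot` plant rows of `plants_per_row` plants. Defaults emulate a
#' perennial ryegrass genomic-selection trial of 50 entries x 10 replicates,
#' plots of 8 x 1.8 m with 3 rows of 32 plants at 25 cm plant and 60 cm row
#' spacing (48,000 plants in 10 blocks), imaged at 2 cm/pixel.
#'
#' Blocks are stacked north to south, separated by `alley_width` of bare
#' soil; plots sit side by side west to east within a block; plant rows run
#' north-south. The trial is georeferenced in a metric UTM CRS.
#'
#' @param n_entries number of entries (breeding lines/cultivars).
#' @param n_reps replicates; one complete replicate per block.
#' @param rows_per_plot plant rows in each plot.
#' @param plants_per_row plants in each row.
#' @param plant_spacing in-row plant spacing, metres.
#' @param row_spacing between-row spacing, metres.
#' @param plot_length plot extent along the row direction, metres.
#' @param plot_width plot extent across rows, metres.
#' @param n_blocks number of blocks; must equal `n_reps`.
#' @param gsd ground sampling distance of rendered imagery, metres/pixel.
#' @param alley_width bare-soil alley between blocks, metres.
#' @param margin bare-soil margin rendered around the trial, metres.
#' @param crop_margin soil margin kept inside the rectification crop, metres.
#' @param lat,lon geographic anchor of the trial's north-west corner.
#' @param rng_seed integer seed driving all downstream randomness.
#' @return an object of class `trial_layout` (a list).
#' @export
trial_layout <- function(n_entries = 50, n_reps = 10, rows_per_plot = 3,
                         plants_per_row = 32, plant_spacing = 0.25,
                         row_spacing = 0.60, plot_length = 8.0,
                         plot_width = 1.8, n_blocks = n_reps, gsd = 0.02,
                         alley_width = 1.0, margin = 2.5, crop_margin = 0.5,
                         lat = -37.8464, lon = 142.0737, rng_seed = 42L) {
  counts <- c(n_entries = n_entries, n_reps = n_reps,
              rows_per_plot = rows_per_plot, plants_per_row = plants_per_row,
              n_blocks = n_blocks)
  if (any(counts < 1)) {
    bad <- names(counts)[which(counts < 1)[1]]
    stop("invalid layout: ", bad, " must be >= 1", call. = FALSE)
  }
  if (n_blocks != n_reps) {
    stop("invalid layout: n_blocks must equal n_reps (one replicate per block)",
         call. = FALSE)
  }
  if (plants_per_row * plant_spacing > plot_length + 1e-9) {
    stop("invalid layout: plants_per_row * plant_spacing exceeds plot_length",
         call. = FALSE)
  }
  if (rows_per_plot * row_spacing > plot_width + row_spacing + 1e-9) {
    stop("invalid layout: rows_per_plot * row_spacing exceeds plot_width + row_spacing",
         call. = FALSE)
  }
  for (v in c(plant_spacing, row_spacing, plot_length, plot_width, gsd)) {
    if (v <= 0) stop("invalid layout: spacings and sizes must be > 0", call. = FALSE)
  }
  origin <- latlon_to_utm(lat, lon)
  structure(
    list(n_entries = n_entries, n_reps = n_reps, rows_per_plot = rows_per_plot,
         plants_per_row = plants_per_row, plant_spacing = plant_spacing,
         row_spacing = row_spacing, plot_length = plot_length,
         plot_width = plot_width, n_blocks = n_blocks, gsd = gsd,
         alley_width = alley_width, margin = margin, crop_margin = crop_margin,
         origin_x = origin$easting[1], origin_y = origin$northing[1],
         crs = origin$crs[1], zone = origin$zone[1], south = lat < 0,
         rng_seed = as.integer(rng_seed)),
    class = "trial_layout"
  )
}

#' @export
print.trial_layout <- function(x, ...) {
  cat(sprintf(paste0("<trial_layout> %d entries x %d blocks = %d plots; ",
                     "%d rows x %d plants per plot (%s plants)\n"),
              x$n_entries, x$n_blocks, x$n_entries * x$n_reps,
              x$rows_per_plot, x$plants_per_row,
              format(x$n_entries * x$n_reps * x$rows_per_plot *
                       x$plants_per_row, big.mark = ",")))
  invisible(x)
}

# Derived world geometry shared by generator and renderer.
layout_geometry <- function(layout) {
  l <- layout
  trial_w <- l$n_entries * l$plot_width
  trial_h <- l$n_blocks * l$plot_length + (l$n_blocks - 1) * l$alley_width
  list(
    trial_w = trial_w, trial_h = trial_h,
    # trial area bounds (world): origin = NW corner of trial area
    x0 = l$origin_x, x1 = l$origin_x + trial_w,
    y1 = l$origin_y, y0 = l$origin_y - trial_h,
    block_top = l$origin_y - (seq_len(l$n_blocks) - 1) *
      (l$plot_length + l$alley_width)
  )
}

#' Generate ground-truth tables for a synthetic trial
#'
#' Lays every plant out on the layout grid, randomizes entries to plots
#' within blocks (randomized complete block design) and draws per-plant
#' traits: peak NDVI, height and canopy radius, each with an entry-level
#' effect so that genotypes differ. Deterministic for a fixed
#' `layout$rng_seed`.
#'
#' @param layout a [trial_layout].
#' @return a list of class `trial_truth` with tibbles `plants`, `rows`,
#'   `plots` (world-coordinate geometry + traits) and the `layout`.
#' @export
generate_layout <- function(layout) {
  stopifnot(inherits(layout, "trial_layout"))
  l <- layout
  g <- layout_geometry(l)
  with_seed(l$rng_seed + 1L, {
    entry_ndvi <- rnorm(l$n_entries, 0, 0.05)
    entry_height <- rnorm(l$n_entries, 0, 2)

    plots <- tidyr::expand_grid(block = seq_len(l$n_blocks),
                                plot_index = seq_len(l$n_entries)) |>
      dplyr::group_by(.data$block) |>
      dplyr::mutate(entry = sample(l$n_entries)) |>
      dplyr::ungroup() |>
      dplyr::mutate(
        plot_id = sprintf("B%02d-P%02d", .data$block, .data$plot_index),
        wx0 = g$x0 + (.data$plot_index - 1) * l$plot_width,
        wx1 = .data$wx0 + l$plot_width,
        wy1 = g$block_top[.data$block],
        wy0 = .data$wy1 - l$plot_length
      )

    rows <- tidyr::expand_grid(
      plots[c("plot_id", "block", "plot_index", "entry", "wx0", "wy0", "wy1")],
      row_in_plot = seq_len(l$rows_per_plot)
    ) |>
      dplyr::mutate(
        row_id = sprintf("%s-R%d", .data$plot_id, .data$row_in_plot),
        center_x = .data$wx0 + l$row_spacing / 2 +
          (.data$row_in_plot - 1) * l$row_spacing,
        # row index across the whole block, west to east
        row_in_block = (.data$plot_index - 1) * l$rows_per_plot +
          .data$row_in_plot
      ) |>
      dplyr::select("row_id", "plot_id", "block", "plot_index", "entry",
                    "row_in_plot", "row_in_block", "center_x",
                    wy0 = "wy0", wy1 = "wy1")

    plants <- tidyr::expand_grid(
      rows[c("row_id", "plot_id", "block", "plot_index", "entry",
             "row_in_plot", "row_in_block", "center_x", "wy1")],
      position = seq_len(l$plants_per_row)
    ) |>
      dplyr::mutate(
        plant_id = sprintf("%s-N%02d", .data$row_id, .data$position),
        x = .data$center_x,
        y = .data$wy1 - l$plant_spacing / 2 -
          (.data$position - 1) * l$plant_spacing,
        # one latent vigor per plant (entry effect + plant-to-plant noise)
        # drives greenness, height and canopy size jointly, as in a real
        # sward where big plants are also greener and taller
        vigor = clamp(runif(dplyr::n(), 0.15, 0.95) +
                        entry_ndvi[.data$entry] * 4, 0.05, 1),
        radius = 0.09 + 0.06 * .data$vigor,
        true_ndvi = 0.40 + 0.55 * .data$vigor,
        true_height = pmax(2, 4 + 22 * .data$vigor + rnorm(dplyr::n(), 0, 1.5) +
                             entry_height[.data$entry])
      ) |>
      dplyr::select("plant_id", "row_id", "plot_id", "block", "plot_index",
                    "entry", "row_in_plot", "row_in_block", "position",
                    "x", "y", "vigor", "radius", "true_ndvi", "true_height")
  })
  structure(list(plants = plants, rows = rows, plots = plots, layout = l),
            class = "trial_truth")
}

#' @export
print.trial_truth <- function(x, ...) {
  cat(sprintf("<trial_truth> %d plots, %d rows, %d plants\n",
              nrow(x$plots), nrow(x$rows), nrow(x$plants)))
  invisible(x)
}
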