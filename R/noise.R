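# Binary white-noise stimulus on a coarse spherical grid, used for
# receptive-field mapping. Frames are derived from a single master seed by
# a per-frame counter so any frame can be regenerated out of order.

#' Spherical white-noise grid specification
#'
#' Divides the arena field of view into square cells of `cell` degrees.
#' With the default 5-degree cells over a 180 x 140 degree field of view
#' the grid is 36 x 28 cells; the cell count must come out integer. The
#' elevation extent is anchored at the top of the screen (elevation
#' `el_top`, default 50 degrees, i.e. 140 degrees of polar angle from the
#' bowl pole) and extends downward.
#'
#' @param cell Cell size, degrees of solid-angle resolution.
#' @param az_extent,el_extent Field of view covered, degrees.
#' @param rate Update rate in Hz.
#' @param seed Master seed; every frame is reproducible from it.
#' @param el_top Elevation of the upper grid edge, degrees.
#' @return An object of class `noise_grid`.
#' @examples
#' noise_grid()            # 36 x 28 cells
#' noise_grid(cell = 2.8)  # fine grid for neuronal receptive fields
#' @export
noise_grid <- function(cell = 5, az_extent = 180, el_extent = 140,
                       rate = 60, seed = 1, el_top = 50) {
  az_bins <- az_extent / cell
  el_bins <- el_extent / cell
  if (abs(az_bins - round(az_bins)) > 1e-9 ||
      abs(el_bins - round(el_bins)) > 1e-9) {
    stop_domain("`cell` must divide both `az_extent` and `el_extent`")
  }
  structure(list(cell = cell, az_bins = as.integer(round(az_bins)),
                 el_bins = as.integer(round(el_bins)),
                 az_range = c(-az_extent / 2, az_extent / 2),
                 el_range = c(el_top - el_extent, el_top),
                 rate = rate, seed = as.integer(seed)),
            class = "noise_grid")
}

#' @export
print.noise_grid <- function(x, ...) {
  cat(sprintf(
    "Noise grid: %d x %d cells of %g deg (az x el), %g Hz, seed %d\n",
    x$az_bins, x$el_bins, x$cell, x$rate, x$seed))
  invisible(x)
}

# cell-center coordinates
grid_az <- function(grid) {
  grid$az_range[1] + (seq_len(grid$az_bins) - 0.5) * grid$cell
}

grid_el <- function(grid) {
  grid$el_range[2] - (seq_len(grid$el_bins) - 0.5) * grid$cell
}

# cell centers for every linear pixel index (column-major: elevation
# fastest, matching as.vector of an el_bins x az_bins matrix)
grid_cell_centers <- function(grid) {
  el <- rep(grid_el(grid), times = grid$az_bins)
  az <- rep(grid_az(grid), each = grid$el_bins)
  cbind(az = az, el = el)
}

#' Single binary white-noise frame
#'
#' Each cell is an independent Bernoulli(1/2) draw in `{0, 1}`. The frame
#' is addressed by index: the same `(seed, frame)` pair always yields the
#' same pattern, regardless of which frames were generated before.
#'
#' @param grid A [noise_grid()].
#' @param frame 1-based frame index.
#' @return An `el_bins x az_bins` matrix of 0/1 values (row 1 = top
#'   elevation).
#' @export
noise_frame <- function(grid, frame) {
  stopifnot(inherits(grid, "noise_grid"), frame >= 1)
  set.seed(derive_seed(grid$seed, frame))
  matrix(as.numeric(stats::runif(grid$el_bins * grid$az_bins) < 0.5),
         grid$el_bins, grid$az_bins)
}

#' Generate a binary white-noise frame sequence
#'
#' @param grid A [noise_grid()].
#' @param duration_s Sequence duration in seconds.
#' @return An object of class `noise_stimulus`: list with `frames` (a
#'   `n_frames x n_cells` matrix of 0/1, cells in column-major
#'   elevation-fastest order) and the `grid`.
#' @export
binary_noise <- function(grid, duration_s) {
  stopifnot(inherits(grid, "noise_grid"), duration_s > 0)
  n <- round(duration_s * grid$rate)
  p <- grid$el_bins * grid$az_bins
  frames <- matrix(0, n, p)
  for (f in seq_len(n)) frames[f, ] <- as.vector(noise_frame(grid, f))
  structure(list(frames = frames, grid = grid, n_frames = n,
                 duration_s = duration_s),
            class = "noise_stimulus")
}

#' @export
print.noise_stimulus <- function(x, ...) {
  cat(sprintf("Binary noise stimulus: %d frames (%g s at %g Hz) on a %d x %d grid\n",
              x$n_frames, x$duration_s, x$grid$rate, x$grid$az_bins,
              x$grid$el_bins))
  invisible(x)
}

#' Extract a time window of a noise stimulus
#'
#' Returns the contiguous sub-sequence of frames starting at `start_s`
#' (inclusive) of length `duration_s`, as a `noise_stimulus` sharing the
#' same grid. Used, e.g., to estimate kernels in sliding windows across a
#' session.
#'
#' @param stim A [binary_noise()] stimulus.
#' @param start_s Window start, seconds from the sequence start.
#' @param duration_s Window length, seconds.
#' @return A `noise_stimulus`.
#' @export
noise_window <- function(stim, start_s, duration_s) {
  stopifnot(inherits(stim, "noise_stimulus"))
  i0 <- round(start_s * stim$grid$rate)
  n <- round(duration_s * stim$grid$rate)
  if (i0 < 0 || i0 + n > stim$n_frames) stop_domain("window out of range")
  structure(list(frames = stim$frames[i0 + seq_len(n), , drop = FALSE],
                 grid = stim$grid, n_frames = n, duration_s = duration_s),
            class = "noise_stimulus")
}

#' Convert one noise frame to a spherical texture
#'
#' @param stim A [binary_noise()] sequence (or a [noise_grid()] plus a
#'   frame matrix).
#' @param frame Frame index.
#' @return A [spherical_texture()] over the grid extents.
#' @export
noise_frame_texture <- function(stim, frame) {
  stopifnot(inherits(stim, "noise_stimulus"))
  g <- stim$grid
  vals <- matrix(stim$frames[frame, ], g$el_bins, g$az_bins)
  spherical_texture(vals, az_range = g$az_range, el_range = g$el_range)
}
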