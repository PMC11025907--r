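# Spatiotemporal receptive-field estimation by sliding reverse correlation
# of a binary white-noise stimulus against a frame-locked response trace.

#' Frame-locked response trace
#'
#' @param samples Numeric response values, one per stimulus frame.
#' @param rate Sampling rate in Hz (equal to the stimulus frame rate after
#'   per-frame integration).
#' @param offset Alignment offset to the stimulus frame clock, seconds.
#' @return An object of class `response_trace`.
#' @export
response_trace <- function(samples, rate, offset = 0) {
  if (any(!is.finite(samples))) stop_domain("response must be finite")
  if (rate <= 0) stop_domain("`rate` must be positive")
  structure(list(samples = as.numeric(samples), rate = rate,
                 offset = offset),
            class = "response_trace")
}

#' @export
print.response_trace <- function(x, ...) {
  cat(sprintf("Response trace: %d samples at %g Hz (%.1f s), mean %.4g\n",
              length(x$samples), x$rate, length(x$samples) / x$rate,
              mean(x$samples)))
  invisible(x)
}

new_strf <- function(values, az_range, el_range, rate, grid = NULL) {
  structure(list(values = values, az_range = az_range, el_range = el_range,
                 rate = rate, lags = seq_len(dim(values)[1]) - 1L,
                 grid = grid),
            class = "strf")
}

#' Spatiotemporal receptive field by sliding reverse correlation
#'
#' Estimates the linear kernel `k[lag, y, x]` as the average product of the
#' contrast-coded stimulus (`0/1` recoded to `-1/+1`) at `t - lag` with the
#' mean-subtracted response at `t`:
#' `k[lag, y, x] = 1/N * sum_t s[t - lag, y, x] * (r[t] - mean(r))`,
#' with `N` the number of summed frames at that lag. This equals the naive
#' triple-loop summation exactly; the implementation evaluates it as one
#' matrix product per lag.
#'
#' @param stim A [binary_noise()] stimulus.
#' @param response A [response_trace()] with one sample per stimulus frame.
#' @param max_lag Largest lag in frames (`>= 0`, `< n_frames`).
#' @return An object of class `strf`: `values` is a
#'   `(max_lag + 1) x el_bins x az_bins` array (lag 0 first), plus the grid
#'   geometry and frame rate.
#' @export
reverse_correlate <- function(stim, response, max_lag = 20) {
  stopifnot(inherits(stim, "noise_stimulus"),
            inherits(response, "response_trace"))
  Tn <- stim$n_frames
  if (length(response$samples) != Tn) {
    stop_domain(sprintf("response has %d samples but the stimulus %d frames",
                        length(response$samples), Tn))
  }
  if (max_lag < 0 || max_lag >= Tn) {
    stop_domain("`max_lag` must be in [0, n_frames)")
  }
  r <- response$samples - mean(response$samples)
  F <- stim$frames
  p <- ncol(F)
  g <- stim$grid
  K <- matrix(0, max_lag + 1L, p)
  for (lag in 0:max_lag) {
    rw <- r[seq.int(lag + 1L, Tn)]
    # sum_t (2*F[t-lag] - 1)*r[t] == 2 * sum_t F[t]*r[t+lag] - sum(rw);
    # zero-padding r instead of subsetting F avoids copying the (large)
    # frame matrix at every lag
    rpad <- c(rw, rep(0, lag))
    K[lag + 1L, ] <- (2 * crossprod(F, rpad) - sum(rw)) / (Tn - lag)
  }
  arr <- array(0, c(max_lag + 1L, g$el_bins, g$az_bins))
  for (l in seq_len(max_lag + 1L)) {
    arr[l, , ] <- matrix(K[l, ], g$el_bins, g$az_bins)
  }
  new_strf(arr, g$az_range, g$el_range, g$rate, grid = g)
}

#' @export
print.strf <- function(x, ...) {
  d <- dim(x$values)
  pk <- strf_peak(x)
  cat(sprintf(
    "Spatiotemporal RF: %d lags x %d x %d (el x az), %g Hz\n",
    d[1], d[2], d[3], x$rate))
  cat(sprintf("  peak |k| = %.4g at lag %d (%.0f ms), az %.1f, el %.1f deg\n",
              pk$value, pk$lag, 1000 * pk$lag / x$rate, pk$az, pk$el))
  invisible(x)
}

#' @export
plot.strf <- function(x, lag = NULL, ...) {
  if (is.null(lag)) lag <- strf_peak(x)$lag
  m <- x$values[lag + 1L, , ]
  az <- seq(x$az_range[1], x$az_range[2], length.out = ncol(m))
  el <- seq(x$el_range[1], x$el_range[2], length.out = nrow(m))
  zl <- max(abs(m))
  graphics::image(az, el, t(m[nrow(m):1, ]),
                  col = grDevices::hcl.colors(64, "Blue-Red"),
                  zlim = c(-zl, zl), xlab = "azimuth (deg)",
                  ylab = "elevation (deg)",
                  main = sprintf("kernel at lag %d", lag),
                  useRaster = TRUE, asp = 1, ...)
  invisible(x)
}

# position (az/el center coordinates) and value of the global |kernel| peak
strf_peak <- function(x) {
  d <- dim(x$values)
  i <- which.max(abs(x$values))
  lag <- (i - 1) %% d[1]
  rest <- (i - 1) %/% d[1]
  row <- rest %% d[2] + 1
  col <- rest %/% d[2] + 1
  daz <- diff(x$az_range) / d[3]
  del <- diff(x$el_range) / d[2]
  list(lag = as.integer(lag), row = row, col = col,
       az = x$az_range[1] + (col - 0.5) * daz,
       el = x$el_range[2] - (row - 0.5) * del,
       value = abs(x$values[i]), sign = sign(x$values[i]))
}

# time-collapsed spatial magnitude map at the dominant lag
strf_spatial_map <- function(x) {
  pk <- strf_peak(x)
  abs(x$values[pk$lag + 1L, , ])
}

#' Spatial center of mass of a receptive field
#'
#' Magnitude-weighted center of mass of the time-collapsed (dominant-lag)
#' spatial map, restricted to the region above `threshold` times the peak
#' so that far-field estimation noise does not bias the centroid.
#'
#' @param x An [reverse_correlate()] `strf`.
#' @param threshold Fraction of the peak magnitude below which weights are
#'   zeroed (default 0.5, the half-maximum region).
#' @return Named numeric `c(az, el)` in degrees.
#' @export
rf_center <- function(x, threshold = 0.5) {
  stopifnot(inherits(x, "strf"))
  M <- strf_spatial_map(x)
  if (max(M) <= 0) stop_domain("all-zero kernel: receptive-field center undefined")
  W <- ifelse(M >= threshold * max(M), M, 0)
  d <- dim(M)
  daz <- diff(x$az_range) / d[2]
  del <- diff(x$el_range) / d[1]
  az <- x$az_range[1] + (seq_len(d[2]) - 0.5) * daz
  el <- x$el_range[2] - (seq_len(d[1]) - 0.5) * del
  c(az = sum(W %*% az) / sum(W),
    el = sum(el %*% W) / sum(W))
}

#' Recenter a receptive field to the distortion-free map center
#'
#' Rotates every lag's spatial map on the sphere so the receptive-field
#' center lands at azimuth/elevation (0, 0), resampling onto a finer
#' equirectangular grid. This removes the equirectangular stretching that
#' inflates off-center receptive fields and makes estimates at different
#' screen positions directly comparable.
#'
#' @param x An `strf`.
#' @param center `c(az, el)` to rotate to the origin; default
#'   [rf_center()] of `x`.
#' @param out_res Output resolution in degrees per pixel.
#' @param out_az,out_el Output extents (degrees).
#' @return A recentered `strf` on the output grid.
#' @export
recenter_rf <- function(x, center = NULL, out_res = 1,
                        out_az = c(-60, 60), out_el = c(-60, 60)) {
  stopifnot(inherits(x, "strf"))
  if (is.null(center)) center <- rf_center(x)
  R <- rotation_between(center[1], center[2], 0, 0)
  nl <- dim(x$values)[1]
  nr <- round(diff(out_el) / out_res)
  nc <- round(diff(out_az) / out_res)
  out <- array(0, c(nl, nr, nc))
  for (l in seq_len(nl)) {
    out[l, , ] <- rotate_field(x$values[l, , ], x$az_range, x$el_range,
                               R, c(nr, nc), out_az, out_el)
  }
  new_strf(out, out_az, out_el, x$rate)
}

#' Receptive-field summary statistics
#'
#' Summarizes a (typically recentered) kernel: center of mass, area of the
#' half-maximum contour of the time-averaged spatial map, full width at
#' half maximum of 1D azimuth/elevation slices through the peak, the
#' temporal kernel at the spatial peak, and a noise-floor flag (peak below
#' `noise_mult` times the SD of far-lag weights).
#'
#' @param x An `strf`.
#' @param time_window Lag window (seconds) over which the spatial map is
#'   averaged; default `c(0, 0.1)`.
#' @param baseline_lags Frame lags treated as far-field noise baseline.
#' @param noise_mult Peak-detection multiple of the baseline SD.
#' @return An object of class `rf_summary`.
#' @export
rf_stats <- function(x, time_window = c(0, 0.1), baseline_lags = 10:20,
                     noise_mult = 3) {
  stopifnot(inherits(x, "strf"))
  d <- dim(x$values)
  lag_s <- x$lags / x$rate
  win <- which(lag_s >= time_window[1] & lag_s <= time_window[2])
  if (length(win) == 0) stop_domain("empty time window")
  M <- apply(x$values[win, , , drop = FALSE], c(2, 3), mean)
  pk <- which(abs(M) == max(abs(M)), arr.ind = TRUE)[1, ]
  s <- sign(M[pk[1], pk[2]])
  P <- s * M
  half <- max(P) / 2
  daz <- diff(x$az_range) / d[3]
  del <- diff(x$el_range) / d[2]
  az <- x$az_range[1] + (seq_len(d[3]) - 0.5) * daz
  el <- x$el_range[2] - (seq_len(d[2]) - 0.5) * del
  # solid-angle weighted area (deg^2) of the half-maximum contour
  cellarea <- daz * del * cos(deg2rad(el))
  size <- sum((P >= half) * matrix(cellarea, d[2], d[3]))
  fwhm_az <- fwhm_1d(az, P[pk[1], ])
  fwhm_el <- fwhm_1d(rev(el), rev(P[, pk[2]]))
  tk <- x$values[, pk[1], pk[2]]
  base <- x$lags %in% baseline_lags
  floor_sd <- if (any(base)) stats::sd(tk[base]) else NA_real_
  out <- list(center = rf_center(x),
              size_deg2 = size, fwhm_az = fwhm_az, fwhm_el = fwhm_el,
              temporal_kernel = tk, lag_s = lag_s, polarity = s,
              peak_value = max(P),
              below_noise_floor = is.finite(floor_sd) &&
                max(P) < noise_mult * floor_sd,
              time_window = time_window)
  class(out) <- "rf_summary"
  out
}

#' @export
print.rf_summary <- function(x, ...) {
  cat(sprintf(
    "RF summary: center (%.1f, %.1f) deg, FWHM az %.1f / el %.1f deg, half-max area %.0f deg^2\n",
    x$center[1], x$center[2], x$fwhm_az, x$fwhm_el, x$size_deg2))
  cat(sprintf("  polarity %s, peak %.4g%s\n",
              if (x$polarity >= 0) "ON" else "OFF", x$peak_value,
              if (x$below_noise_floor) " (below noise floor!)" else ""))
  invisible(x)
}

# interpolated full width at half maximum of a 1D profile (coords ascending)
fwhm_1d <- function(coords, profile) {
  m <- which.max(profile)
  half <- profile[m] / 2
  left <- NA_real_
  for (i in seq_len(m - 1)) {
    j <- m - i
    if (profile[j] < half) {
      left <- coords[j] + (coords[j + 1] - coords[j]) *
        (half - profile[j]) / (profile[j + 1] - profile[j])
      break
    }
  }
  right <- NA_real_
  for (j in seq.int(m, length(profile) - 1)) {
    if (profile[j + 1] < half) {
      right <- coords[j] + (coords[j + 1] - coords[j]) *
        (profile[j] - half) / (profile[j] - profile[j + 1])
      break
    }
  }
  right - left
}

#' Temporal support and peak lag of a kernel
#'
#' `kernel_temporal_support()` counts the consecutive frames, starting at
#' lag 0, whose kernel value at the spatial peak exceeds `noise_mult`
#' times the SD of the far-lag baseline. `kernel_peak_lag()` returns the
#' lag (frames) of the largest-magnitude kernel value.
#'
#' @param x An `strf`.
#' @param baseline_lags Frame lags treated as noise baseline.
#' @param noise_mult Threshold multiple of the baseline SD.
#' @return An integer number of frames.
#' @export
kernel_temporal_support <- function(x, baseline_lags = 10:20,
                                    noise_mult = 3) {
  stopifnot(inherits(x, "strf"))
  pk <- strf_peak(x)
  tk <- pk$sign * x$values[, pk$row, pk$col]
  base <- x$lags %in% baseline_lags
  thr <- noise_mult * stats::sd(tk[base])
  n <- 0L
  for (v in tk) {
    if (v > thr) n <- n + 1L else break
  }
  n
}

#' @rdname kernel_temporal_support
#' @export
kernel_peak_lag <- function(x) {
  stopifnot(inherits(x, "strf"))
  strf_peak(x)$lag
}
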