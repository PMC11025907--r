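# Tethered-flight behavior analysis: wingbeat-envelope quantification from
# top-view images, open-loop optomotor trace processing, and closed-loop
# fixation simulation and statistics.

#' Wingbeat amplitudes from a top-view image
#'
#' Background-subtracts the image and returns the weighted mean pixel value
#' under the left and right wing masks, an indirect measure of the left and
#' right wingbeat amplitude; their difference approximates yaw torque.
#' Illumination differences between the two sides are compensated by the
#' per-mask weights.
#'
#' @param image Image matrix.
#' @param masks A [wingbeat_masks()] object.
#' @param background Background image matrix (same dimensions); default 0.
#' @return Named numeric `c(L, R, diff)` with `diff = L - R`.
#' @export
wingbeat_amplitudes <- function(image, masks, background = 0) {
  stopifnot(inherits(masks, "wingbeat_masks"), is.matrix(image))
  if (is.matrix(background) && !all(dim(background) == dim(image))) {
    stop_domain("background dimensions do not match the image")
  }
  if (!any(masks$left) || !any(masks$right)) {
    stop_domain("empty wingbeat mask")
  }
  if (!all(dim(masks$left) == dim(image))) {
    stop_domain("mask dimensions do not match the image")
  }
  d <- image - background
  L <- masks$weights[1] * mean(d[masks$left])
  R <- masks$weights[2] * mean(d[masks$right])
  c(L = L, R = R, diff = L - R)
}

#' Left/right steering signal
#'
#' @param L,R Per-frame left/right wingbeat amplitudes.
#' @param rate Acquisition rate in Hz (default 120, a typical top-view
#'   camera).
#' @return An object of class `steering_signal` with `L`, `R`, `diff` and
#'   `rate`.
#' @export
steering_signal <- function(L, R, rate = 120) {
  if (length(L) != length(R)) stop_domain("L and R must have equal length")
  if (any(!is.finite(L)) || any(!is.finite(R))) {
    stop_domain("steering signals must be finite")
  }
  structure(list(L = as.numeric(L), R = as.numeric(R), diff = L - R,
                 rate = rate),
            class = "steering_signal")
}

# resample a vector to a new rate by linear interpolation
resample_linear <- function(x, rate_in, rate_out) {
  t_in <- (seq_along(x) - 1) / rate_in
  t_out <- seq(0, t_in[length(t_in)], by = 1 / rate_out)
  stats::approx(t_in, x, xout = t_out, rule = 2)$y
}

# symmetric Gaussian FIR smoothing (sd = tau seconds, truncated at
# +/- 3 tau, edge-replicated)
gaussian_smooth <- function(x, rate, tau) {
  half <- max(1L, round(3 * tau * rate))
  t <- (-half:half) / rate
  k <- exp(-t^2 / (2 * tau^2))
  k <- k / sum(k)
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, k, sides = 2))[half + seq_along(x)]
}

#' Process an open-loop steering trace
#'
#' The standard optomotor preprocessing chain: resample the left and right
#' wingbeat amplitudes to `out_rate`, low-pass filter with a symmetric
#' Gaussian kernel (`tau` seconds), subtract the two sides (left - right),
#' and subtract the mean of the reference period (the first
#' `timeline$reference_s` seconds, recorded without visual motion) as
#' baseline.
#'
#' @param signal A [steering_signal()] covering the full trial.
#' @param timeline A [trial_timeline()].
#' @param out_rate Output rate, Hz.
#' @param tau Gaussian smoothing SD in seconds.
#' @return A data.frame with columns `time` and `response`.
#' @export
process_steering <- function(signal, timeline, out_rate = 50, tau = 0.4) {
  stopifnot(inherits(signal, "steering_signal"),
            inherits(timeline, "trial_timeline"))
  if (length(signal$L) / signal$rate < timeline$total_s - 1e-9) {
    stop_domain(sprintf("trial is %.2f s but the timeline needs %g s",
                        length(signal$L) / signal$rate, timeline$total_s))
  }
  L <- gaussian_smooth(resample_linear(signal$L, signal$rate, out_rate),
                       out_rate, tau)
  R <- gaussian_smooth(resample_linear(signal$R, signal$rate, out_rate),
                       out_rate, tau)
  d <- L - R
  time <- (seq_along(d) - 1) / out_rate
  ref <- time < timeline$reference_s
  data.frame(time = time, response = d - mean(d[ref]))
}

#' Optomotor response from a clockwise/counterclockwise trial pair
#'
#' Processes both trials with [process_steering()], rectifies them
#' (counterclockwise responses are sign-flipped) and averages, then
#' summarizes the response as the mean over a 6-second window starting two
#' seconds after stimulus onset.
#'
#' @param cw,ccw [steering_signal()]s for the clockwise and
#'   counterclockwise trials.
#' @param timeline A [trial_timeline()].
#' @param out_rate,tau Passed to [process_steering()].
#' @param window_start_s,window_s Averaging window relative to stimulus
#'   onset, seconds.
#' @return A list with `trace` (data.frame `time`, `cw`, `ccw`,
#'   `rectified`) and `scalar` (the time-averaged response strength).
#' @export
optomotor_response <- function(cw, ccw, timeline = trial_timeline(),
                               out_rate = 50, tau = 0.4,
                               window_start_s = 2, window_s = 6) {
  pc <- process_steering(cw, timeline, out_rate, tau)
  pcc <- process_steering(ccw, timeline, out_rate, tau)
  n <- min(nrow(pc), nrow(pcc))
  rect <- (pc$response[seq_len(n)] - pcc$response[seq_len(n)]) / 2
  time <- pc$time[seq_len(n)]
  w0 <- timeline$reference_s + window_start_s
  win <- time >= w0 & time < w0 + window_s
  list(trace = data.frame(time = time, cw = pc$response[seq_len(n)],
                          ccw = pcc$response[seq_len(n)],
                          rectified = rect),
       scalar = mean(rect[win]))
}

#' Closed-loop state and update step
#'
#' In closed loop the steering signal (wingbeat amplitude difference) is
#' coupled to the yaw position of the displayed texture: each step advances
#' the yaw by `gain * steering` deg/s, clipped to `+/- max_rate`, and wraps
#' it into `[0, 360)`.
#'
#' @param yaw Initial texture yaw, degrees.
#' @param gain Feedback gain in deg/s per unit steering signal.
#' @param max_rate Largest achievable rotation speed, deg/s.
#' @return For `closed_loop_state()`: an object of class
#'   `closed_loop_state`. `closed_loop_step()` returns the updated state.
#' @export
closed_loop_state <- function(yaw = 0, gain = 1, max_rate = 140) {
  stopifnot(max_rate > 0)
  structure(list(yaw = yaw %% 360, gain = gain, max_rate = max_rate),
            class = "closed_loop_state")
}

#' @rdname closed_loop_state
#' @param state A `closed_loop_state`.
#' @param steering Steering signal value.
#' @param dt Time step in seconds.
#' @export
closed_loop_step <- function(state, steering, dt) {
  stopifnot(inherits(state, "closed_loop_state"), dt > 0)
  rate <- state$gain * steering
  rate <- max(-state$max_rate, min(state$max_rate, rate))
  state$yaw <- (state$yaw + rate * dt) %% 360
  state
}

#' Simulate a closed-loop fixation trial
#'
#' Runs a steering policy against a texture in closed loop at the given
#' frame rate (zero-order hold on the steering command within a frame,
#' optional fixed loop delay). The policy is a function
#' `policy(texture, yaw, t)` returning a steering value; see
#' [dark_seeking_policy()].
#'
#' @param texture A [spherical_texture()] panorama.
#' @param policy Steering policy function.
#' @param duration_s Trial duration, seconds.
#' @param rate Loop rate, Hz.
#' @param gain,max_rate Closed-loop coupling, see [closed_loop_state()].
#' @param yaw0 Initial yaw; `NULL` draws it uniformly from the seed.
#' @param delay_s Loop delay in seconds (rounded to whole frames).
#' @param seed Integer seed (initial yaw and any policy noise).
#' @return A data.frame with columns `time`, `yaw`, `steering`.
#' @export
simulate_fixation <- function(texture, policy, duration_s = 60, rate = 60,
                              gain = 1, max_rate = 140, yaw0 = NULL,
                              delay_s = 0, seed = 1) {
  stopifnot(inherits(texture, "spherical_texture"))
  set.seed(derive_seed(seed, 7100))
  if (is.null(yaw0)) yaw0 <- stats::runif(1, 0, 360)
  st <- closed_loop_state(yaw0, gain, max_rate)
  n <- round(duration_s * rate)
  delay <- round(delay_s * rate)
  yaw <- numeric(n)
  steer <- numeric(n)
  buffer <- rep(0, max(1, delay))
  for (i in seq_len(n)) {
    yaw[i] <- st$yaw
    s <- policy(texture, st$yaw, (i - 1) / rate)
    if (delay > 0) {
      buffer <- c(buffer[-1], s)
      s <- buffer[1]
    }
    steer[i] <- s
    st <- closed_loop_step(st, s, 1 / rate)
  }
  data.frame(time = (seq_len(n) - 1) / rate, yaw = yaw, steering = steer)
}

#' Dark-seeking steering policy
#'
#' A simple synthetic "fly": it looks at the frontal +/- 90 degrees of the
#' horizon band of the texture (as displaced by the current yaw), finds the
#' azimuth of minimum luminance, and steers proportionally so as to bring
#' that azimuth in front, with optional Gaussian steering noise.
#'
#' @param k Proportional steering gain (per degree of target azimuth).
#' @param noise_sd SD of additive steering noise.
#' @param el Elevation at which the panorama is sampled, degrees.
#' @param step Sampling resolution of the frontal field, degrees.
#' @param seed Integer seed for the steering noise.
#' @return A policy function for [simulate_fixation()].
#' @export
dark_seeking_policy <- function(k = 0.05, noise_sd = 0, el = -20,
                                step = 2, seed = 1) {
  rng <- new.env(parent = emptyenv())
  rng$count <- 0
  function(texture, yaw, t) {
    rel <- seq(-90, 90, by = step)
    lum <- sample_texture(texture, rel - yaw, rep(el, length(rel)),
                          fill = 1, method = "bilinear")
    target <- rel[which.min(lum)]
    s <- -k * target
    if (noise_sd > 0) {
      rng$count <- rng$count + 1
      set.seed(derive_seed(seed, 7200 + rng$count))
      s <- s + stats::rnorm(1, 0, noise_sd)
    }
    s
  }
}

#' Azimuthal fixation probability density
#'
#' Resamples a yaw trajectory to `resample_rate`, bins it over `[0, 360)`
#' and normalizes so the density integrates to one (units 1/degree).
#'
#' @param yaw Yaw trajectory in degrees.
#' @param rate Trajectory sampling rate, Hz.
#' @param bin_width Bin width in degrees (must divide 360).
#' @param resample_rate Resampling rate, Hz.
#' @return A data.frame with bin `mid` (degrees) and `density` (1/degree).
#' @export
fixation_density <- function(yaw, rate, bin_width = 3.6,
                             resample_rate = 50) {
  if (length(yaw) < 2) stop_domain("trajectory too short")
  if (abs(360 / bin_width - round(360 / bin_width)) > 1e-9) {
    stop_domain("`bin_width` must divide 360")
  }
  # resample on the unwrapped trajectory so bins near 0/360 are not split
  steps <- wrap_angle_diff(diff(yaw))
  unwrapped <- yaw[1] + c(0, cumsum(steps))
  y <- resample_linear(unwrapped, rate, resample_rate) %% 360
  nb <- round(360 / bin_width)
  cuts <- seq(0, 360, by = bin_width)
  counts <- tabulate(findInterval(y, cuts, rightmost.closed = TRUE), nb)
  data.frame(mid = cuts[-1] - bin_width / 2,
             density = counts / (length(y) * bin_width))
}

#' Average fixation densities across trials
#'
#' @param densities List of [fixation_density()] data.frames on the same
#'   bins.
#' @return A data.frame with `mid` and the across-trial mean `density`.
#' @export
average_fixation_density <- function(densities) {
  stopifnot(length(densities) >= 1)
  mid <- densities[[1]]$mid
  dens <- rowMeans(vapply(densities, function(d) d$density,
                          numeric(length(mid))))
  data.frame(mid = mid, density = dens)
}
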