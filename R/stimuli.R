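# Stimulus synthesis. All stimuli are generated as full-panorama
# equirectangular spherical textures (azimuth -180..180 wrapping, elevation
# -90..90) at a configurable resolution, and are later cropped/remapped by
# the projection stage.

stimulus_grid <- function(res) {
  if (abs(360 / res - round(360 / res)) > 1e-9 ||
      abs(180 / res - round(180 / res)) > 1e-9) {
    stop_domain("`res` must divide both 360 and 180 degrees")
  }
  nr <- as.integer(round(180 / res))
  nc <- as.integer(round(360 / res))
  az <- -180 + (seq_len(nc) - 0.5) * res
  el <- 90 - (seq_len(nr) - 0.5) * res
  list(nr = nr, nc = nc, az = az, el = el)
}

#' Virtual-cylinder grating texture
#'
#' A vertical square-wave (or sine) grating lining the inside of a virtual
#' cylinder that extends from the horizon downward by `height` degrees of
#' elevation, on a uniform background. The grating wraps seamlessly: the
#' spatial `period` must divide 360.
#'
#' @param period Spatial grating period in degrees of azimuth.
#' @param height Angular height of the textured band below the horizon,
#'   degrees in `(0, 90]`.
#' @param contrast Michelson contrast of the grating in `[0, 1]`.
#' @param yaw Azimuthal phase shift of the pattern, degrees.
#' @param background Background luminance.
#' @param waveform `"square"` or `"sine"`.
#' @param res Texture resolution, degrees per pixel.
#' @return A [spherical_texture()].
#' @examples
#' tex <- cylinder_grating(period = 30, height = 36, res = 2)
#' @export
cylinder_grating <- function(period = 30, height = 36, contrast = 1,
                             yaw = 0, background = 0.5,
                             waveform = c("square", "sine"), res = 1) {
  waveform <- match.arg(waveform)
  if (360 %% period != 0) {
    stop_domain("`period` must divide 360 degrees for seamless wraparound")
  }
  if (height <= 0 || height > 90) {
    stop_domain("`height` must be in (0, 90] degrees")
  }
  g <- stimulus_grid(res)
  ph <- sin(2 * pi * (g$az - yaw) / period)
  wave <- if (waveform == "square") sign(ph) else ph
  wave[wave == 0] <- 1
  rowband <- g$el <= 0 & g$el >= -height
  vals <- matrix(background, g$nr, g$nc)
  vals[rowband, ] <- rep(0.5 + 0.5 * contrast * wave, each = sum(rowband))
  spherical_texture(vals)
}

#' Advisory conversion between cylinder proportions and angular height
#'
#' For an observer on the axis at the height of the top rim of a cylinder
#' of diameter `d` and height `h`, the cylinder wall spans
#' `atan(2 / (d/h))` degrees of elevation below the horizon. The mapping is
#' advisory: experimental descriptions may quote `d/h` ratios and angular
#' heights that follow other conventions, so both are accepted
#' independently by the stimulus functions.
#'
#' @param d_h Diameter-to-height ratio.
#' @param height Angular height in degrees.
#' @return The converted quantity.
#' @export
cylinder_angular_height <- function(d_h) rad2deg(atan(2 / d_h))

#' @rdname cylinder_angular_height
#' @export
cylinder_dh_ratio <- function(height) 2 / tan(deg2rad(height))

#' Moving-edge texture
#'
#' A luminance step at azimuth `start + velocity * t`. A bright edge has
#' luminance 1 behind the edge (at smaller azimuth) and 0 ahead; a dark
#' edge is its complement.
#'
#' @param polarity `"bright"` or `"dark"`.
#' @param velocity Edge velocity in deg/s.
#' @param t Time in seconds.
#' @param start Edge azimuth at `t = 0`, degrees.
#' @param res Texture resolution, degrees per pixel.
#' @return A [spherical_texture()].
#' @export
moving_edge <- function(polarity = c("bright", "dark"), velocity, t = 0,
                        start = -90, res = 1) {
  polarity <- match.arg(polarity)
  g <- stimulus_grid(res)
  pos <- start + velocity * t
  behind <- as.numeric(g$az <= pos)
  if (polarity == "dark") behind <- 1 - behind
  spherical_texture(matrix(rep(behind, each = g$nr), g$nr, g$nc))
}

#' Dark vertical bar texture
#'
#' A dark bar of the given angular width on a bright background, wrap-safe
#' in azimuth.
#'
#' @param width Bar width in degrees, `0 < width < 360`.
#' @param position Bar center azimuth in degrees (any value; wraps).
#' @param bar,background Bar and background luminance.
#' @param res Texture resolution, degrees per pixel.
#' @return A [spherical_texture()].
#' @export
dark_bar <- function(width = 15, position = 0, bar = 0, background = 1,
                     res = 1) {
  if (width <= 0 || width >= 360) stop_domain("`width` must be in (0, 360)")
  g <- stimulus_grid(res)
  inbar <- abs(wrap_angle_diff(g$az, position)) <= width / 2
  col <- ifelse(inbar, bar, background)
  spherical_texture(matrix(rep(col, each = g$nr), g$nr, g$nc))
}

#' Interior panorama of an infinitely tall cuboid with graded edges
#'
#' Emulates an arrangement of four inward-facing screens around the
#' observer: uniform wall luminance with a smooth (raised-cosine) luminance
#' dip into each of the four vertical edges at 90-degree spacing. Opposite
#' edges share their central luminance; the defaults render two slightly
#' darker (0.67) and two lighter (0.77) edges on 0.98 walls.
#'
#' @param edge_lums Central luminances of the four edges, in azimuth order
#'   at `yaw + c(0, 90, 180, 270)` degrees.
#' @param wall_lum Wall luminance between edges.
#' @param yaw Azimuthal rotation of the whole texture, degrees.
#' @param edge_halfwidth Half-width of each edge's luminance dip, degrees
#'   (must be <= 45 so dips do not overlap).
#' @param res Texture resolution, degrees per pixel.
#' @return A [spherical_texture()].
#' @export
cuboid_interior <- function(edge_lums = c(0.67, 0.77, 0.67, 0.77),
                            wall_lum = 0.98, yaw = 0, edge_halfwidth = 10,
                            res = 1) {
  stopifnot(length(edge_lums) == 4, all(edge_lums >= 0 & edge_lums <= 1),
            wall_lum >= 0, wall_lum <= 1)
  if (edge_halfwidth <= 0 || edge_halfwidth > 45) {
    stop_domain("`edge_halfwidth` must be in (0, 45] degrees")
  }
  g <- stimulus_grid(res)
  lum <- rep(wall_lum, g$nc)
  for (k in 1:4) {
    d <- abs(wrap_angle_diff(g$az, yaw + (k - 1) * 90)) / edge_halfwidth
    dip <- ifelse(d <= 1, 0.5 * (1 + cos(pi * d)), 0)
    lum <- lum - (wall_lum - edge_lums[k]) * dip
  }
  spherical_texture(matrix(rep(lum, each = g$nr), g$nr, g$nc))
}

#' Trial timeline for behavioral experiments
#'
#' A trial phase structure: a reference period without motion, a
#' stimulation period, and a post-stimulation period, contiguous in that
#' order (defaults 2 + 6 + 6 = 14 s).
#'
#' @param reference_s,stimulation_s,post_s Phase durations in seconds.
#' @return An object of class `trial_timeline`.
#' @export
trial_timeline <- function(reference_s = 2, stimulation_s = 6, post_s = 6) {
  stopifnot(reference_s > 0, stimulation_s > 0, post_s >= 0)
  structure(list(reference_s = reference_s, stimulation_s = stimulation_s,
                 post_s = post_s,
                 total_s = reference_s + stimulation_s + post_s),
            class = "trial_timeline")
}

#' @export
print.trial_timeline <- function(x, ...) {
  cat(sprintf("Trial timeline: %g s reference + %g s stimulation + %g s post = %g s\n",
              x$reference_s, x$stimulation_s, x$post_s, x$total_s))
  invisible(x)
}

#' Frame-accurate yaw/phase table of a motion trial
#'
#' Expands a [trial_timeline()] into one row per stimulus frame: phase
#' label and pattern yaw. Yaw is 0 during the reference phase, advances at
#' `velocity` (sign set by `direction`) during stimulation, and holds its
#' final value during the post phase.
#'
#' @param timeline A [trial_timeline()].
#' @param direction `"cw"`, `"ccw"` or `"static"`. Clockwise (seen from
#'   above) advances yaw positively.
#' @param velocity Pattern speed during stimulation, deg/s.
#' @param rate Frame rate, Hz.
#' @return A data.frame with columns `frame`, `time`, `phase`, `yaw`.
#' @export
trial_frames <- function(timeline, direction = c("cw", "ccw", "static"),
                         velocity = 60, rate = 60) {
  stopifnot(inherits(timeline, "trial_timeline"))
  direction <- match.arg(direction)
  n <- round(timeline$total_s * rate)
  n_ref <- round(timeline$reference_s * rate)
  n_stim <- round(timeline$stimulation_s * rate)
  frame <- seq_len(n)
  time <- (frame - 1) / rate
  phase <- rep("post", n)
  phase[frame <= n_ref] <- "reference"
  phase[frame > n_ref & frame <= n_ref + n_stim] <- "stimulation"
  sgn <- switch(direction, cw = 1, ccw = -1, static = 0)
  stim_elapsed <- pmax(0, pmin(time - timeline$reference_s,
                               timeline$stimulation_s))
  data.frame(frame = frame, time = time, phase = phase,
             yaw = sgn * velocity * stim_elapsed)
}

#' Randomized trial schedule
#'
#' Produces a seed-reproducible randomized ordering of stimulus conditions
#' (e.g. rotation directions, cylinder sizes), each paired with a
#' frame-accurate [trial_frames()] table, plus a per-frame texture
#' generator.
#'
#' @param timeline A [trial_timeline()].
#' @param conditions Data frame of conditions, one row per trial type;
#'   must contain a `direction` column.
#' @param stimulus_fun Function of `yaw` (degrees) returning a
#'   [spherical_texture()] for one frame; called lazily.
#' @param velocity Pattern speed, deg/s.
#' @param rate Frame rate, Hz.
#' @param seed Integer seed for the ordering.
#' @return An object of class `trial_schedule`: list with `order` (row
#'   indices into `conditions` in presentation order), `trials` (list of
#'   per-trial frame tables) and `frame_texture(trial, frame)`.
#' @export
schedule_trials <- function(timeline, conditions, stimulus_fun,
                            velocity = 60, rate = 60, seed = 1) {
  stopifnot(inherits(timeline, "trial_timeline"), is.data.frame(conditions),
            "direction" %in% names(conditions))
  set.seed(derive_seed(seed, 0))
  ord <- sample(nrow(conditions))
  trials <- lapply(ord, function(i) {
    trial_frames(timeline, conditions$direction[i], velocity, rate)
  })
  frame_texture <- function(trial, frame) {
    stimulus_fun(trials[[trial]]$yaw[frame])
  }
  structure(list(order = ord, conditions = conditions, trials = trials,
                 frame_texture = frame_texture, rate = rate,
                 timeline = timeline, seed = seed),
            class = "trial_schedule")
}
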