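# Synthetic rig: software stand-ins for the hardware around the screen --
# a photodiode, a linear-nonlinear model neuron, a panoramic camera at the
# observer position, and a top-view wingbeat-image generator. All are
# deterministic given a seed. They emulate idealized devices; none is a
# fit to recorded data.

#' Photodiode model
#'
#' A light sensor integrating luminance over an acceptance region of the
#' visual field, with optional latency and additive Gaussian noise. The
#' acceptance profile is either a hard azimuth/elevation window
#' (`"boxcar"`) or a circular Gaussian of given FWHM centered on
#' `center` (`"gaussian"`, weighting by angular distance on the sphere and
#' by cell solid angle).
#'
#' @param az_window,el_window Acceptance window, degrees (boxcar profile).
#' @param center `c(az, el)` of a Gaussian acceptance profile, degrees.
#' @param fwhm Full width at half maximum of the Gaussian profile, degrees.
#' @param profile `"boxcar"` or `"gaussian"`.
#' @param latency Response latency in seconds.
#' @param gain Output gain.
#' @param noise_sd SD of additive Gaussian output noise.
#' @return An object of class `photodiode_model`.
#' @export
photodiode_model <- function(az_window = c(-15, 15), el_window = c(-35, -5),
                             center = NULL, fwhm = 20,
                             profile = c("boxcar", "gaussian"),
                             latency = 0, gain = 1, noise_sd = 0) {
  profile <- match.arg(profile)
  if (noise_sd < 0) stop_domain("`noise_sd` must be >= 0")
  if (profile == "gaussian" && is.null(center)) {
    stop_domain("a gaussian profile needs `center = c(az, el)`")
  }
  structure(list(az_window = az_window, el_window = el_window,
                 center = center, fwhm = fwhm, profile = profile,
                 latency = latency, gain = gain, noise_sd = noise_sd),
            class = "photodiode_model")
}

# normalized acceptance weights of a sensor over the cells of a noise grid
sensor_weights <- function(model, grid) {
  ctr <- grid_cell_centers(grid)
  if (model$profile == "boxcar") {
    w <- as.numeric(ctr[, "az"] >= model$az_window[1] &
                      ctr[, "az"] <= model$az_window[2] &
                      ctr[, "el"] >= model$el_window[1] &
                      ctr[, "el"] <= model$el_window[2])
  } else {
    d <- angular_distance(dir_from_azel(ctr[, "az"], ctr[, "el"]),
                          dir_from_azel(rep(model$center[1], nrow(ctr)),
                                        rep(model$center[2], nrow(ctr))))
    sigma <- model$fwhm / 2.3548
    w <- exp(-d^2 / (2 * sigma^2)) * cos(deg2rad(ctr[, "el"]))
  }
  if (sum(w) <= 0) {
    stop_domain("sensor acceptance region lies outside the stimulated grid")
  }
  w / sum(w)
}

#' Simulate a photodiode response to a noise stimulus
#'
#' The response at frame `t` is `gain` times the acceptance-weighted mean
#' luminance at frame `t - latency` plus Gaussian noise; the first frames
#' (before one latency has elapsed) hold the first available value.
#'
#' @param stim A [binary_noise()] stimulus.
#' @param model A [photodiode_model()].
#' @param seed Integer seed for the output noise.
#' @return A [response_trace()] at the stimulus frame rate.
#' @export
photodiode_respond <- function(stim, model, seed = 1) {
  stopifnot(inherits(stim, "noise_stimulus"),
            inherits(model, "photodiode_model"))
  w <- sensor_weights(model, stim$grid)
  drive <- as.numeric(stim$frames %*% w)
  lat <- round(model$latency * stim$grid$rate)
  if (lat > 0) {
    drive <- c(rep(drive[1], lat), drive[seq_len(length(drive) - lat)])
  }
  out <- model$gain * drive
  if (model$noise_sd > 0) {
    set.seed(derive_seed(seed, 7001))
    out <- out + stats::rnorm(length(out), 0, model$noise_sd)
  }
  response_trace(out, stim$grid$rate)
}

#' Linear-nonlinear model neuron
#'
#' A visual neuron with a circular Gaussian spatial receptive field, a
#' biphasic temporal kernel (two alpha-function lobes of opposite sign),
#' a saturating static nonlinearity, and additive output noise. The
#' defaults echo the qualitative filter properties of an OFF-center
#' medullary interneuron -- a negative lobe peaking near 50 ms with a weak
#' positive rebound near 570 ms -- and are purely synthetic, not a fit to
#' any recording.
#'
#' @param center Receptive-field center `c(az, el)`, degrees.
#' @param fwhm Spatial FWHM in degrees.
#' @param polarity `+1` (ON) or `-1` (OFF).
#' @param lobe1_peak,lobe2_peak Peak latencies of the two temporal lobes,
#'   seconds.
#' @param lobe2_amp Amplitude of the rebound lobe relative to the (unit)
#'   first lobe.
#' @param kernel_support Temporal kernel length in seconds.
#' @param offset,slope,saturation Static nonlinearity
#'   `offset + saturation * tanh(slope * x / saturation)`.
#' @param noise_sd SD of additive Gaussian output noise.
#' @return An object of class `ln_neuron_model`.
#' @export
ln_neuron_model <- function(center = c(0, 0), fwhm = 10, polarity = -1,
                            lobe1_peak = 0.05, lobe2_peak = 0.57,
                            lobe2_amp = 0.15, kernel_support = 1,
                            offset = 0, slope = 1, saturation = 5,
                            noise_sd = 0) {
  stopifnot(fwhm > 0, polarity %in% c(-1, 1), lobe1_peak > 0,
            lobe2_peak > lobe1_peak, kernel_support > lobe2_peak,
            noise_sd >= 0, saturation > 0)
  structure(list(center = center, fwhm = fwhm, polarity = polarity,
                 lobe1_peak = lobe1_peak, lobe2_peak = lobe2_peak,
                 lobe2_amp = lobe2_amp, kernel_support = kernel_support,
                 offset = offset, slope = slope, saturation = saturation,
                 noise_sd = noise_sd),
            class = "ln_neuron_model")
}

# discretized biphasic temporal kernel at the stimulus frame rate
neuron_temporal_kernel <- function(model, rate) {
  t <- seq(0, model$kernel_support, by = 1 / rate)
  alpha_lobe <- function(t, tau) (t / tau) * exp(1 - t / tau)
  k <- -alpha_lobe(t, model$lobe1_peak) +
    model$lobe2_amp * alpha_lobe(t, model$lobe2_peak)
  if (model$polarity > 0) k <- -k
  k
}

#' Simulate a linear-nonlinear neuron's response to a noise stimulus
#'
#' The contrast-coded stimulus (`0/1` to `-1/+1`) is weighted by the
#' Gaussian spatial receptive field, convolved (causally) with the
#' biphasic temporal kernel, passed through the saturating nonlinearity,
#' and corrupted with seeded Gaussian noise.
#'
#' @param stim A [binary_noise()] stimulus.
#' @param model An [ln_neuron_model()].
#' @param seed Integer seed for the output noise.
#' @return A [response_trace()] at the stimulus frame rate.
#' @export
neuron_respond <- function(stim, model, seed = 1) {
  stopifnot(inherits(stim, "noise_stimulus"),
            inherits(model, "ln_neuron_model"))
  g <- stim$grid
  ctr <- grid_cell_centers(g)
  if (model$center[1] < g$az_range[1] || model$center[1] > g$az_range[2] ||
      model$center[2] < g$el_range[1] || model$center[2] > g$el_range[2]) {
    stop_domain("receptive-field center lies outside the stimulated field of view")
  }
  d <- angular_distance(dir_from_azel(ctr[, "az"], ctr[, "el"]),
                        dir_from_azel(rep(model$center[1], nrow(ctr)),
                                      rep(model$center[2], nrow(ctr))))
  sigma <- model$fwhm / 2.3548
  w <- exp(-d^2 / (2 * sigma^2)) * cos(deg2rad(ctr[, "el"]))
  w <- w / sum(w)
  drive <- as.numeric((2 * stim$frames - 1) %*% w)
  k <- neuron_temporal_kernel(model, g$rate)
  lin <- stats::filter(c(rep(0, length(k) - 1), drive), k, sides = 1)
  lin <- as.numeric(lin)[length(k) - 1 + seq_along(drive)]
  out <- model$offset +
    model$saturation * tanh(model$slope * lin / model$saturation)
  if (model$noise_sd > 0) {
    set.seed(derive_seed(seed, 7002))
    out <- out + stats::rnorm(length(out), 0, model$noise_sd)
  }
  response_trace(out, g$rate)
}

#' Capture the screen with a virtual panoramic camera
#'
#' An ideal panoramic camera at the observer position: for every output
#' view direction it reports the luminance of the projector pixel that
#' illuminates the (ideal Lambertian) screen in that direction; directions
#' that miss the screen return the background value. Optionally a
#' multiplicative shading field (same dimensions as the output) can emulate
#' imperfect brightness uniformity.
#'
#' @param image Projector-image matrix (as produced by [apply_maps()]).
#' @param maps The [build_pixel_maps()] used to drive the projector.
#' @param out_dims `c(rows, cols)` of the equirectangular capture.
#' @param az_range,el_range Extents of the capture; default the screen FOV.
#' @param background Value reported off-screen.
#' @param shading Optional multiplicative shading matrix.
#' @return A [spherical_texture()] of the capture, with attribute
#'   `"on_screen"` (logical matrix).
#' @export
camera_capture <- function(image, maps, out_dims = NULL, az_range = NULL,
                           el_range = NULL, background = 0,
                           shading = NULL) {
  stopifnot(inherits(maps, "pixel_map"), is.matrix(image))
  if (!all(dim(image) == dim(maps$valid))) {
    stop_domain("projector image dimensions do not match the pixel maps")
  }
  model <- maps$model
  if (is.null(az_range)) az_range <- c(-maps$az_span / 2, maps$az_span / 2)
  if (is.null(el_range)) el_range <- maps$alpha_range - 90
  if (is.null(out_dims)) {
    out_dims <- c(round(diff(el_range)), round(diff(az_range)))
  }
  nr <- out_dims[1]
  nc <- out_dims[2]
  az <- az_range[1] + (seq_len(nc) - 0.5) * diff(az_range) / nc
  el <- el_range[2] - (seq_len(nr) - 0.5) * diff(el_range) / nr
  AZ <- matrix(rep(az, each = nr), nr, nc)
  EL <- matrix(rep(el, times = nc), nr, nc)
  alpha <- EL + 90
  H <- model$image_height_px
  W <- model$image_width_px
  rho <- H * alpha / 180
  xpx <- rho * sin(deg2rad(AZ))
  ypx <- rho * cos(deg2rad(AZ))
  col <- round(xpx + W / 2 + 0.5)
  row <- round(H - ypx + 0.5)
  on_screen <- alpha >= maps$alpha_range[1] & alpha <= maps$alpha_range[2] &
    abs(AZ) <= maps$az_span / 2 &
    row >= 1 & row <= H & col >= 1 & col <= W
  vals <- matrix(background, nr, nc)
  vals[on_screen] <- image[cbind(row[on_screen], col[on_screen])]
  if (!is.null(shading)) {
    stopifnot(all(dim(shading) == out_dims))
    vals <- vals * shading
  }
  out <- spherical_texture(pmin(pmax(vals, 0), 1), az_range, el_range)
  attr(out, "on_screen") <- on_screen
  out
}

#' Synthetic top-view wingbeat image
#'
#' Renders a stylized top view of a tethered flying insect: a bright body
#' silhouette along the vertical axis plus left and right wing-envelope
#' sectors sweeping forward from straight-back by the given envelope
#' angles, with optional seeded pixel noise. Larger envelope angles produce
#' larger bright sectors on the corresponding side.
#'
#' @param l_angle,r_angle Left/right wing-envelope angles in degrees,
#'   within `(0, 160)`.
#' @param dims Image `c(rows, cols)`; default 524 x 656.
#' @param wing_lum,body_lum Luminance of wings and body.
#' @param noise_sd SD of additive pixel noise (clipped to `[0, 1]`).
#' @param seed Integer seed for the noise.
#' @return A numeric image matrix in `[0, 1]`.
#' @export
wingbeat_image <- function(l_angle, r_angle, dims = c(524, 656),
                           wing_lum = 0.7, body_lum = 1, noise_sd = 0,
                           seed = 1) {
  stopifnot(l_angle > 0, l_angle < 160, r_angle > 0, r_angle < 160)
  nr <- dims[1]
  nc <- dims[2]
  cx <- (nc + 1) / 2
  cy <- (nr + 1) / 2
  X <- matrix(rep(seq_len(nc) - cx, each = nr), nr, nc)
  Y <- matrix(rep(cy - seq_len(nr), times = nc), nr, nc)
  r <- sqrt(X^2 + Y^2)
  theta <- rad2deg(atan2(X, Y))       # 0 = up (anterior), +right, -left
  r_wing <- 0.42 * min(nr, nc)
  r_body <- 0.06 * min(nr, nc)
  img <- matrix(0, nr, nc)
  wings <- r <= r_wing & r > r_body / 2 &
    ((theta <= -180 + l_angle & theta < 0) |
       (theta >= 180 - r_angle & theta > 0))
  img[wings] <- wing_lum
  body <- (X / r_body)^2 + (Y / (3 * r_body))^2 <= 1
  img[body] <- body_lum
  if (noise_sd > 0) {
    set.seed(derive_seed(seed, 7003))
    img <- img + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
  }
  pmin(pmax(img, 0), 1)
}

#' Left/right wingbeat analysis masks
#'
#' Boolean masks covering the rear-left and rear-right image quadrants out
#' to the wing radius, the regions swept by the wing envelopes in
#' [wingbeat_image()]-style top views.
#'
#' @param dims Image `c(rows, cols)`.
#' @param weights Length-2 multiplicative weights `c(left, right)`
#'   compensating illumination differences.
#' @return An object of class `wingbeat_masks`: list with logical `left`,
#'   `right` matrices and `weights`.
#' @export
wingbeat_masks <- function(dims = c(524, 656), weights = c(1, 1)) {
  stopifnot(all(weights > 0))
  nr <- dims[1]
  nc <- dims[2]
  cx <- (nc + 1) / 2
  cy <- (nr + 1) / 2
  X <- matrix(rep(seq_len(nc) - cx, each = nr), nr, nc)
  Y <- matrix(rep(cy - seq_len(nr), times = nc), nr, nc)
  r <- sqrt(X^2 + Y^2)
  r_wing <- 0.45 * min(nr, nc)
  rear <- Y < 0 & r <= r_wing
  structure(list(left = rear & X < 0, right = rear & X > 0,
                 weights = weights),
            class = "wingbeat_masks")
}
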