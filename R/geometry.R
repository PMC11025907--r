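#' Viewing direction of an ommatidium in the elevation plane
#'
#' The compound eye is modeled as a sphere of viewing directions; in the
#' two-dimensional cross-section through the optical axis the facet looking
#' at elevation angle `alpha` (measured from the device axis) views along the
#' unit vector `c(cos(alpha), sin(alpha))`.
#'
#' @param alpha Elevation angle(s) in radians, strictly inside `(0, pi)`.
#' @return A length-2 unit vector, or an `n x 2` matrix for vector input.
#' @export
fly_ray <- function(alpha) {
  check_alpha(alpha)
  out <- cbind(cos(alpha), sin(alpha))
  colnames(out) <- c("x", "y")
  if (length(alpha) == 1L) drop(out) else out
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || any(!is.finite(alpha))) {
    stop_domain("`alpha` must be finite numeric radians")
  }
  if (any(alpha <= 0 | alpha >= pi)) {
    stop_domain("`alpha` must lie strictly inside (0, pi) radians")
  }
  invisible(alpha)
}

#' Projection line of the projector for a given elevation angle
#'
#' Commercial projectors produce uniform pixel spacing on a planar screen,
#' so the image-plane height of a pixel is linear in the fraction of the
#' image it sits at. With a 100% upward offset the ray addressing elevation
#' parameter `alpha` leaves the projector at `(d_proj, 0)` with direction
#' `c(1, alpha / (pi * r))`: the full image height sweeps `alpha` from 0 to
#' `pi`.
#'
#' @param alpha Elevation angle in radians.
#' @param model A [projector_model()].
#' @return A list with `point` (the projector position) and `direction`
#'   (unnormalized direction vector of the projection line).
#' @export
projector_ray_line <- function(alpha, model) {
  assert_projector_model(model)
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha)) {
    stop_domain("`alpha` must be a single finite number")
  }
  list(point = c(model$d_proj, 0), direction = c(1, alpha / (pi * model$r)))
}

# Stable common scalar of the screen equations:
#   k(alpha) * c(1, tan(alpha)) == s(alpha) * c(cos(alpha), sin(alpha))
# with s = d_proj * alpha / (alpha * cos(alpha) - pi * r * sin(alpha)).
# Multiplying numerator and denominator of the textbook form by cos(alpha)
# removes the tan() blow-up at alpha = pi/2; the removable singularity there
# evaluates to the analytic limit automatically.
profile_scale <- function(alpha, model, tol = 1e-8) {
  denom <- alpha * cos(alpha) - pi * model$r * sin(alpha)
  bad <- abs(denom) < tol * max(1, pi * model$r)
  if (any(bad)) {
    stop_domain(sprintf(
      "screen profile is singular near alpha = %s rad (denominator ~ 0)",
      paste(signif(alpha[bad], 6), collapse = ", ")))
  }
  model$d_proj * alpha / denom
}

#' Point of the bowl-shaped screen profile
#'
#' Intersects the viewing direction of the facet at elevation `alpha`
#' ([fly_ray()]) with the projection line of the projector pixel addressing
#' the same elevation ([projector_ray_line()]). The trajectory of these
#' intersection points is the screen profile that keeps the number of
#' projector pixels per ommatidium constant along the elevation. In closed
#' form the intersection is
#' `d_proj * alpha / (alpha - pi * r * tan(alpha)) * c(1, tan(alpha))`,
#' evaluated here in a numerically stable form that also covers the
#' removable singularity at `alpha = pi/2` by its analytic limit
#' `c(0, -d_proj / (2 * r))`.
#'
#' @inheritParams fly_ray
#' @param model A [projector_model()].
#' @param tol Singularity guard: an error is raised when the (stabilized)
#'   denominator falls below this tolerance.
#' @return A length-2 point, or an `n x 2` matrix for vector `alpha`.
#' @export
profile_point <- function(alpha, model, tol = 1e-8) {
  assert_projector_model(model)
  check_alpha(alpha)
  s <- profile_scale(alpha, model, tol)
  out <- cbind(x = s * cos(alpha), y = s * sin(alpha))
  if (length(alpha) == 1L) drop(out) else out
}

#' Point on the bowl-shaped screen surface
#'
#' The 3D screen surface is the surface of revolution of the profile curve
#' about the optical axis (the x-axis): the profile point at elevation
#' `alpha` is swept through azimuth `beta`, giving
#' `k(alpha) * c(1, tan(alpha) * cos(beta), tan(alpha) * sin(beta))` with
#' `k(alpha) = d_proj * alpha / (alpha - pi * r * tan(alpha))`.
#'
#' @inheritParams profile_point
#' @param beta Azimuth angle(s) in radians, in `[0, 2*pi]`; recycled against
#'   `alpha`.
#' @return A length-3 point, or an `n x 3` matrix for vector input.
#' @export
surface_point <- function(alpha, beta, model, tol = 1e-8) {
  assert_projector_model(model)
  check_alpha(alpha)
  if (any(!is.finite(beta)) || any(beta < 0 | beta > 2 * pi)) {
    stop_domain("`beta` must lie in [0, 2*pi] radians")
  }
  n <- max(length(alpha), length(beta))
  alpha <- rep_len(alpha, n)
  beta <- rep_len(beta, n)
  s <- profile_scale(alpha, model, tol)
  out <- cbind(x = s * cos(alpha),
               y = s * sin(alpha) * cos(beta),
               z = s * sin(alpha) * sin(beta))
  if (n == 1L) drop(out) else out
}

#' Sample the screen profile over an elevation range
#'
#' Generates `n` profile points at uniformly spaced elevation angles. The
#' default field of view of 15 to 140 degrees along the elevation matches a
#' bowl that leaves the pole region (occupied by the holder) and the extreme
#' rim out of the printed screen.
#'
#' @param model A [projector_model()].
#' @param alpha_range Length-2 numeric, elevation range in degrees.
#' @param n Number of samples (`>= 2`); endpoints are included exactly.
#' @param tol Passed to [profile_point()].
#' @return An object of class `screen_profile`: a list with `alpha`
#'   (radians, strictly increasing), `points` (`n x 2` matrix) and the
#'   generating `model`.
#' @examples
#' pm <- projector_model(d_proj = 100)
#' pr <- screen_profile(pm, n = 50)
#' head(pr$points)
#' @export
screen_profile <- function(model, alpha_range = c(15, 140), n = 200,
                           tol = 1e-8) {
  assert_projector_model(model)
  if (length(alpha_range) != 2 || !all(is.finite(alpha_range)) ||
      alpha_range[1] >= alpha_range[2]) {
    stop_domain("`alpha_range` must be increasing degrees c(min, max)")
  }
  if (n < 2) stop_domain("`n` must be at least 2")
  a <- deg2rad(alpha_range)
  check_alpha(a)
  # refuse ranges containing a true (sign-change) singularity
  fine <- seq(a[1], a[2], length.out = max(512L, 4L * n))
  den <- fine * cos(fine) - pi * model$r * sin(fine)
  flips <- which(diff(sign(den)) != 0 & abs(fine[-1] - pi / 2) > 1e-9)
  flips <- flips[abs(den[flips]) + abs(den[flips + 1L]) >
                   2e-6 * max(1, pi * model$r) &
                 abs(fine[flips] - pi / 2) > 1e-3]
  if (length(flips) > 0) {
    stop_domain(sprintf(
      "profile denominator changes sign inside the range near alpha = %s deg",
      paste(signif(rad2deg(fine[flips]), 5), collapse = ", ")))
  }
  alpha <- seq(a[1], a[2], length.out = n)
  pts <- profile_point(alpha, model, tol)
  structure(list(alpha = alpha, points = pts, model = model,
                 alpha_range_deg = alpha_range),
            class = "screen_profile")
}

#' @export
print.screen_profile <- function(x, ...) {
  cat(sprintf(
    "Bowl screen profile: %d samples, elevation %.6g..%.6g deg\n",
    length(x$alpha), x$alpha_range_deg[1], x$alpha_range_deg[2]))
  cat(sprintf("  x range [%.4g, %.4g], y range [%.4g, %.4g]\n",
              min(x$points[, 1]), max(x$points[, 1]),
              min(x$points[, 2]), max(x$points[, 2])))
  invisible(x)
}

#' @export
plot.screen_profile <- function(x, ...) {
  graphics::plot(x$points, type = "l", asp = 1,
                 xlab = "x (along optical axis)", ylab = "y",
                 main = "Bowl screen profile", ...)
  graphics::points(rbind(x$model$pos_fly, x$model$pos_proj),
                   pch = c(19, 17), col = c("black", "red"))
  invisible(x)
}

#' Triangulated bowl screen surface of revolution
#'
#' Rotationally extrudes the screen profile about the optical axis over
#' `beta_span` degrees of azimuth (default 180, a half bowl) and triangulates
#' the resulting quad grid. The mesh has `n_alpha * n_beta` vertices and
#' `2 * (n_alpha - 1) * (n_beta - 1)` triangles.
#'
#' @inheritParams screen_profile
#' @param beta_span Azimuthal extent of the extrusion in degrees.
#' @param n_alpha,n_beta Grid resolution along elevation and azimuth.
#' @return An object of class `screen_surface`: list with `vertices`
#'   (`V x 3`), `faces` (`F x 3` integer, 1-based), `alpha`, `beta` (radians)
#'   and the `model`.
#' @export
screen_surface <- function(model, alpha_range = c(15, 140),
                           beta_span = 180, n_alpha = 100, n_beta = 90,
                           tol = 1e-8) {
  prof <- screen_profile(model, alpha_range, n_alpha, tol)
  if (beta_span <= 0 || beta_span > 360) {
    stop_domain("`beta_span` must be in (0, 360] degrees")
  }
  if (n_beta < 2) stop_domain("`n_beta` must be at least 2")
  beta <- seq(0, deg2rad(beta_span), length.out = n_beta)
  s <- profile_scale(prof$alpha, model, tol)
  # vertex grid: alpha fastest, beta slowest
  A <- rep(prof$alpha, times = n_beta)
  B <- rep(beta, each = n_alpha)
  S <- rep(s, times = n_beta)
  verts <- cbind(x = S * cos(A), y = S * sin(A) * cos(B),
                 z = S * sin(A) * sin(B))
  idx <- function(i, j) (j - 1L) * n_alpha + i
  i <- rep(seq_len(n_alpha - 1L), times = n_beta - 1L)
  j <- rep(seq_len(n_beta - 1L), each = n_alpha - 1L)
  f1 <- cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
  f2 <- cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
  faces <- rbind(f1, f2)
  structure(list(vertices = verts, faces = faces,
                 alpha = prof$alpha, beta = beta, model = model),
            class = "screen_surface")
}

#' @export
print.screen_surface <- function(x, ...) {
  cat(sprintf(
    "Bowl screen surface: %d vertices, %d triangles (%d x %d grid, %g deg extrusion)\n",
    nrow(x$vertices), nrow(x$faces), length(x$alpha), length(x$beta),
    rad2deg(max(x$beta))))
  invisible(x)
}
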