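# Internal helpers shared across modules. Angles are radians internally;
# every user-facing interface takes degrees.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Signed wrapped difference between two azimuths
#'
#' Returns `a - b` wrapped into `(-180, 180]` degrees, the natural metric on
#' a 360-degree azimuth circle.
#'
#' @param a,b Azimuths in degrees.
#' @return Signed angular difference in degrees.
#' @export
wrap_angle_diff <- function(a, b = 0) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

# Unit view direction from azimuth/elevation in degrees.
# Convention: x points toward (az = 0, el = 0), z up, azimuth increases to
# the left (right-handed).
dir_from_azel <- function(az_deg, el_deg) {
  az <- deg2rad(az_deg)
  el <- deg2rad(el_deg)
  cbind(cos(el) * cos(az), cos(el) * sin(az), sin(el))
}

# Inverse of dir_from_azel(); returns list(az, el) in degrees.
azel_from_dir <- function(v) {
  stopifnot(is.matrix(v), ncol(v) == 3)
  n <- sqrt(rowSums(v^2))
  el <- asin(pmin(1, pmax(-1, v[, 3] / n)))
  az <- atan2(v[, 2], v[, 1])
  list(az = rad2deg(az), el = rad2deg(el))
}

# Row-wise vector norm.
row_norms <- function(m) sqrt(rowSums(m^2))

normalize_rows <- function(m) m / row_norms(m)

# Angular distance (degrees) between unit direction matrices (row-wise).
angular_distance <- function(u, v) {
  d <- pmin(1, pmax(-1, rowSums(u * v)))
  rad2deg(acos(d))
}

#' Rotation matrix from axis and angle
#'
#' Rodrigues' formula. The returned 3x3 matrix is orthonormal with
#' determinant +1 and acts on column direction vectors.
#'
#' @param axis Numeric length-3 rotation axis (need not be unit length).
#' @param angle_deg Rotation angle in degrees (right-hand rule).
#' @return A 3x3 rotation matrix.
#' @export
rotation_axis_angle <- function(axis, angle_deg) {
  stopifnot(length(axis) == 3, is.finite(axis), any(axis != 0))
  a <- axis / sqrt(sum(axis^2))
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, a[3], -a[2],
                -a[3], 0, a[1],
                a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotation carrying one view direction onto another
#'
#' Returns the minimal rotation (about the axis perpendicular to both) that
#' maps the direction `(az_from, el_from)` onto `(az_to, el_to)`.
#'
#' @param az_from,el_from,az_to,el_to Azimuth/elevation in degrees.
#' @return A 3x3 rotation matrix.
#' @export
rotation_between <- function(az_from, el_from, az_to = 0, el_to = 0) {
  u <- drop(dir_from_azel(az_from, el_from))
  v <- drop(dir_from_azel(az_to, el_to))
  ax <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  cth <- sum(u * v)
  if (sqrt(sum(ax^2)) < 1e-12) {
    if (cth > 0) return(diag(3))
    # antipodal: rotate 180 degrees about any perpendicular axis
    ax <- if (abs(u[1]) < 0.9) c(1, 0, 0) - u[1] * u else c(0, 1, 0) - u[2] * u
    return(rotation_axis_angle(ax, 180))
  }
  rotation_axis_angle(ax, rad2deg(atan2(sqrt(sum(ax^2)), cth)))
}

# Derive a per-stream 31-bit seed from a master seed and a counter, so that
# individual noise frames are addressable out of order. Nearby Mersenne
# seeds yield correlated first draws, so the counter is passed through a
# nonlinear mix (two Lehmer rounds and an xor-fold) to spread consecutive
# counters far apart in seed space.
derive_seed <- function(seed, counter) {
  x <- (as.numeric(seed) %% 65521) * 32749 + as.numeric(counter) + 1
  x <- (x * 48271) %% 2147483647
  x <- (x * 69621) %% 2147483647
  xi <- as.integer(x)
  xi <- bitwXor(xi, bitwShiftR(xi, 15))
  as.integer(abs(xi) %% 2147483629L)
}

stop_domain <- function(...) stop(..., call. = FALSE)
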