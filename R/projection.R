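# Equidistant azimuthal projection and precomputed pixel maps.
#
# The bowl screen is built so that the image the projector must display is
# exactly the equidistant azimuthal projection of the sphere around the
# bowl pole: image-plane radius is proportional to the polar angle alpha.
# With a 100% upward lens offset the pole sits at the bottom-center of the
# projector image and the full image height spans alpha = 0..180 degrees.
#
# Projector-image pixel convention: pixel (row r, col c) of an H x W image
# has Cartesian coordinates x = c - 0.5 - W/2 (right positive) and
# y = H - r + 0.5 (up positive, 0 at the bottom edge), in pixels.

#' Equidistant azimuthal projection, forward and inverse
#'
#' Maps a view direction, given as polar angle `alpha` from the bowl pole
#' and azimuth `beta` around it, to polar projector-image coordinates
#' (radius in pixels, angle), and back. The radius is strictly proportional
#' to `alpha`: `radius = H * alpha / 180` for an image height of `H` pixels.
#'
#' @param alpha Polar angle(s) from the projection pole, degrees.
#' @param beta Azimuth angle(s) around the pole, degrees.
#' @param model A [projector_model()] (supplies the image height).
#' @param alpha_max Largest representable polar angle, degrees; larger
#'   `alpha` is flagged `off_screen`.
#' @return For `eqaz_forward()`: list with `radius_px`, `angle_deg`,
#'   `off_screen`. For `eqaz_inverse()`: list with `alpha`, `beta` degrees.
#' @export
eqaz_forward <- function(alpha, beta, model, alpha_max = 180) {
  assert_projector_model(model)
  if (any(alpha < 0)) stop_domain("`alpha` must be >= 0 degrees")
  list(radius_px = model$image_height_px * alpha / 180,
       angle_deg = beta,
       off_screen = alpha > alpha_max)
}

#' @rdname eqaz_forward
#' @param radius_px Image-plane radius in pixels.
#' @param angle_deg Image-plane polar angle in degrees.
#' @export
eqaz_inverse <- function(radius_px, angle_deg, model) {
  assert_projector_model(model)
  list(alpha = 180 * radius_px / model$image_height_px, beta = angle_deg)
}

# polar angle / azimuth of every projector pixel (vectorized, H x W
# matrices), in degrees
projector_pixel_angles <- function(model) {
  W <- model$image_width_px
  H <- model$image_height_px
  x <- matrix(rep(seq_len(W) - 0.5 - W / 2, each = H), H, W)
  y <- matrix(rep(H - seq_len(H) + 0.5, times = W), H, W)
  rho <- sqrt(x^2 + y^2)
  list(alpha = 180 * rho / H, beta = rad2deg(atan2(x, y)))
}

#' Precompute pixel maps from an equirectangular texture to the projector
#'
#' For every projector pixel, computes which texture pixel holds the
#' luminance of the view direction that pixel illuminates on the bowl, and
#' a mask restricting illumination to the screen. The maps depend only on
#' geometry, never on texture content, so they are computed once and reused
#' for every frame. View directions use `elevation = alpha - 90` (the bowl
#' pole points at elevation -90, straight down) and `azimuth = beta`.
#'
#' @param model A [projector_model()].
#' @param texture_dims Length-2 `c(rows, cols)` of the textures the maps
#'   will be applied to.
#' @param az_range,el_range Extents (degrees) of those textures; they must
#'   cover the screen field of view.
#' @param alpha_range Elevation coverage of the screen, degrees of polar
#'   angle from the bowl pole (default 15 to 140).
#' @param az_span Azimuthal extent of the (half-)bowl in degrees.
#' @return An object of class `pixel_map`: integer index matrices
#'   `map_row`, `map_col` (projector-image sized), continuous coordinates
#'   `az`, `el`, logical `valid`, and the generating parameters.
#' @export
build_pixel_maps <- function(model, texture_dims = c(125, 180),
                             az_range = c(-90, 90), el_range = c(-75, 50),
                             alpha_range = c(15, 140), az_span = 180) {
  assert_projector_model(model)
  el_need <- c(alpha_range[1] - 90, alpha_range[2] - 90)
  if (az_range[1] > -az_span / 2 || az_range[2] < az_span / 2 ||
      el_range[1] > el_need[1] || el_range[2] < el_need[2]) {
    stop_domain(sprintf(
      "texture extents (az [%g, %g], el [%g, %g]) do not cover the screen FOV (az +/-%g, el [%g, %g])",
      az_range[1], az_range[2], el_range[1], el_range[2], az_span / 2,
      el_need[1], el_need[2]))
  }
  ang <- projector_pixel_angles(model)
  az <- ang$beta
  el <- ang$alpha - 90
  valid <- ang$alpha >= alpha_range[1] & ang$alpha <= alpha_range[2] &
    abs(az) <= az_span / 2
  nr <- texture_dims[1]
  nc <- texture_dims[2]
  col <- round((az - az_range[1]) / diff(az_range) * nc + 0.5)
  row <- round((el_range[2] - el) / diff(el_range) * nr + 0.5)
  valid <- valid & row >= 1 & row <= nr & col >= 1 & col <= nc
  map_row <- matrix(NA_integer_, nrow(az), ncol(az))
  map_col <- map_row
  map_row[valid] <- as.integer(row[valid])
  map_col[valid] <- as.integer(col[valid])
  structure(list(map_row = map_row, map_col = map_col, az = az, el = el,
                 valid = valid, model = model,
                 texture_dims = as.integer(texture_dims),
                 az_range = az_range, el_range = el_range,
                 alpha_range = alpha_range, az_span = az_span),
            class = "pixel_map")
}

#' @export
print.pixel_map <- function(x, ...) {
  cat(sprintf(
    "Pixel map: %d x %d projector px -> %d x %d texture px; %.1f%% of pixels on screen\n",
    nrow(x$valid), ncol(x$valid), x$texture_dims[1], x$texture_dims[2],
    100 * mean(x$valid)))
  invisible(x)
}

#' Render a texture into a projector image through precomputed maps
#'
#' Nearest-neighbour lookup of the texture at each mapped pixel (chosen
#' over interpolation so the displayed luminances are exactly texture
#' values); masked pixels are black. The operation is linear in the
#' texture.
#'
#' @param tex A [spherical_texture()] whose dimensions match the maps.
#' @param maps A [build_pixel_maps()] result.
#' @param method `"nearest"` (default) or `"bilinear"`.
#' @return Numeric projector-image matrix (rows x cols of the projector).
#' @export
apply_maps <- function(tex, maps, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  stopifnot(inherits(tex, "spherical_texture"), inherits(maps, "pixel_map"))
  if (!all(dim(tex$values) == maps$texture_dims)) {
    stop_domain(sprintf(
      "texture is %d x %d but maps were built for %d x %d",
      nrow(tex$values), ncol(tex$values),
      maps$texture_dims[1], maps$texture_dims[2]))
  }
  out <- matrix(0, nrow(maps$valid), ncol(maps$valid))
  v <- maps$valid
  if (method == "nearest") {
    out[v] <- tex$values[cbind(maps$map_row[v], maps$map_col[v])]
  } else {
    out[v] <- sample_texture(tex, maps$az[v], maps$el[v], fill = 0,
                             method = "bilinear")
  }
  out
}

#' Rotate an equirectangular texture on the sphere
#'
#' Resamples the texture under a 3D rotation of the sphere: each output
#' pixel takes the (bilinearly interpolated) input value at the
#' inverse-rotated view direction. Directions rotated outside the input
#' extents become `fill`.
#'
#' @param tex A [spherical_texture()].
#' @param R A 3x3 rotation matrix, e.g. from [rotation_between()] or
#'   [rotation_axis_angle()].
#' @param out_dims,az_range,el_range Geometry of the output texture;
#'   defaults reuse the input's.
#' @param fill Value for unmapped output pixels.
#' @return A `spherical_texture`.
#' @export
rotate_equirect <- function(tex, R, out_dims = dim(tex$values),
                            az_range = tex$az_range,
                            el_range = tex$el_range, fill = 0) {
  stopifnot(inherits(tex, "spherical_texture"),
            is.matrix(R), all(dim(R) == c(3, 3)))
  vals <- rotate_field(tex$values, tex$az_range, tex$el_range, R,
                       out_dims, az_range, el_range, fill)
  spherical_texture(pmin(pmax(vals, 0), 1), az_range, el_range)
}

# Rotation resampling of an arbitrary-valued equirectangular field (no
# luminance-range restriction): each output pixel bilinearly samples the
# input at the inverse-rotated view direction.
rotate_field <- function(values, az_range, el_range, R,
                         out_dims = dim(values), out_az = az_range,
                         out_el = el_range, fill = 0) {
  tex <- list(values = values, az_range = az_range, el_range = el_range)
  out <- list(values = matrix(0, out_dims[1], out_dims[2]),
              az_range = out_az, el_range = out_el)
  az <- texture_az(out)
  el <- texture_el(out)
  AZ <- matrix(rep(az, each = out_dims[1]), out_dims[1], out_dims[2])
  EL <- matrix(rep(el, times = out_dims[2]), out_dims[1], out_dims[2])
  dirs <- dir_from_azel(c(AZ), c(EL))
  src <- azel_from_dir(dirs %*% R)   # rows are (R^-1 d)^T
  vals <- sample_texture(tex, src$az, src$el, fill = fill,
                         method = "bilinear")
  matrix(vals, out_dims[1], out_dims[2])
}
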