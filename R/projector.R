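#' Projector and viewer geometry model
#'
#' Bundles the constants that determine the bowl-shaped screen: the distance
#' between the observer (at the origin) and the projector, the projector's
#' throw ratio and image aspect ratio, and the image resolution. The product
#' `r = throw_ratio * aspect_ratio` is the single dimensionless constant
#' entering the screen equations. A projection offset of 100% (full upward
#' offset, i.e. the optical axis grazes the lower edge of the image) is
#' required by the screen model and is therefore fixed.
#'
#' @param d_proj Distance from the observer to the projector, in arbitrary
#'   length units (all output geometry is expressed in the same units).
#' @param throw_ratio Projection distance divided by projected image width.
#'   Default 1.4, a common value for compact LED projectors.
#' @param aspect_ratio Image width divided by height. Default 16/9.
#' @param image_width_px,image_height_px Native projector resolution in
#'   pixels. Defaults 1280 x 720.
#' @param offset_fraction Vertical lens offset as a fraction of image height;
#'   must be 1 (100% upward projection).
#' @return An object of class `projector_model`.
#' @examples
#' pm <- projector_model(d_proj = 100)
#' pm$r
#' @export
projector_model <- function(d_proj, throw_ratio = 1.4, aspect_ratio = 16 / 9,
                            image_width_px = 1280L, image_height_px = 720L,
                            offset_fraction = 1) {
  if (!is.numeric(d_proj) || length(d_proj) != 1 || !is.finite(d_proj) ||
      d_proj <= 0) {
    stop_domain("`d_proj` must be a single positive number")
  }
  if (throw_ratio <= 0) stop_domain("`throw_ratio` must be positive")
  if (aspect_ratio <= 0) stop_domain("`aspect_ratio` must be positive")
  if (offset_fraction != 1) {
    stop_domain("the screen model requires a 100% upward projection offset ",
                "(`offset_fraction = 1`)")
  }
  obj <- list(
    d_proj = d_proj,
    throw_ratio = throw_ratio,
    aspect_ratio = aspect_ratio,
    r = throw_ratio * aspect_ratio,
    image_width_px = as.integer(image_width_px),
    image_height_px = as.integer(image_height_px),
    offset_fraction = 1,
    pos_proj = c(d_proj, 0),
    pos_fly = c(0, 0)
  )
  class(obj) <- "projector_model"
  obj
}

#' @export
print.projector_model <- function(x, ...) {
  cat("Projector model\n")
  cat(sprintf("  distance observer-projector : %g\n", x$d_proj))
  cat(sprintf("  throw ratio                 : %g\n", x$throw_ratio))
  cat(sprintf("  aspect ratio                : %g\n", x$aspect_ratio))
  cat(sprintf("  r = throw * aspect          : %g\n", x$r))
  cat(sprintf("  resolution                  : %d x %d px\n",
              x$image_width_px, x$image_height_px))
  invisible(x)
}

is_projector_model <- function(x) inherits(x, "projector_model")

assert_projector_model <- function(x) {
  if (!is_projector_model(x)) {
    stop_domain("expected a `projector_model` object; see ?projector_model")
  }
  invisible(x)
}
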