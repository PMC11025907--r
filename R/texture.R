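#' Equirectangular spherical texture
#'
#' A luminance map of (part of) the sphere in equirectangular layout:
#' rows are elevation (row 1 = highest elevation), columns azimuth
#' (column 1 = leftmost, most negative azimuth), values in `[0, 1]`.
#' Coordinates refer to pixel centers.
#'
#' @param values Numeric matrix of luminance in `[0, 1]`.
#' @param az_range Length-2 azimuth extent in degrees, `c(min, max)`.
#' @param el_range Length-2 elevation extent in degrees, `c(min, max)`.
#' @return An object of class `spherical_texture`.
#' @examples
#' tex <- spherical_texture(matrix(0.5, 125, 180),
#'                          az_range = c(-90, 90), el_range = c(-75, 50))
#' @export
spherical_texture <- function(values, az_range = c(-180, 180),
                              el_range = c(-90, 90)) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (any(!is.finite(values)) || any(values < 0 | values > 1)) {
    stop_domain("texture luminance must be finite and within [0, 1]")
  }
  if (diff(az_range) <= 0 || diff(el_range) <= 0) {
    stop_domain("texture extents must be positive")
  }
  structure(list(values = values, az_range = as.numeric(az_range),
                 el_range = as.numeric(el_range)),
            class = "spherical_texture")
}

#' @export
print.spherical_texture <- function(x, ...) {
  cat(sprintf(
    "Spherical texture %d x %d px, az [%g, %g] deg, el [%g, %g] deg, mean %.3f\n",
    nrow(x$values), ncol(x$values), x$az_range[1], x$az_range[2],
    x$el_range[1], x$el_range[2], mean(x$values)))
  invisible(x)
}

#' @export
plot.spherical_texture <- function(x, ...) {
  az <- texture_az(x)
  el <- texture_el(x)
  graphics::image(az, rev(el), t(x$values[nrow(x$values):1, ]),
                  col = grDevices::gray.colors(256, 0, 1), zlim = c(0, 1),
                  xlab = "azimuth (deg)", ylab = "elevation (deg)",
                  useRaster = TRUE, asp = 1, ...)
  invisible(x)
}

# pixel-center coordinate vectors
texture_az <- function(tex) {
  n <- ncol(tex$values)
  tex$az_range[1] + (seq_len(n) - 0.5) * diff(tex$az_range) / n
}

texture_el <- function(tex) {
  n <- nrow(tex$values)
  tex$el_range[2] - (seq_len(n) - 0.5) * diff(tex$el_range) / n
}

# continuous (row, col) index of an (az, el) position; row/col 1 maps to the
# first pixel center
texture_index <- function(tex, az, el) {
  nr <- nrow(tex$values)
  nc <- ncol(tex$values)
  col <- (az - tex$az_range[1]) / diff(tex$az_range) * nc + 0.5
  row <- (tex$el_range[2] - el) / diff(tex$el_range) * nr + 0.5
  list(row = row, col = col)
}

# Bilinear sample at continuous az/el (degrees); positions outside the
# extents return `fill`. If the texture spans 360 degrees of azimuth the
# azimuth axis wraps.
sample_texture <- function(tex, az, el, fill = 0,
                           method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  nr <- nrow(tex$values)
  nc <- ncol(tex$values)
  wraps <- isTRUE(all.equal(diff(tex$az_range), 360))
  if (wraps) {
    az <- tex$az_range[1] + (az - tex$az_range[1]) %% 360
  }
  ix <- texture_index(tex, az, el)
  inside <- az >= tex$az_range[1] & az <= tex$az_range[2] &
    el >= tex$el_range[1] & el <= tex$el_range[2]
  out <- rep(fill, length(az))
  if (!any(inside)) return(out)
  r <- ix$row[inside]
  cl <- ix$col[inside]
  if (method == "nearest") {
    ri <- pmin(nr, pmax(1L, round(r)))
    ci <- pmin(nc, pmax(1L, round(cl)))
    if (wraps) ci <- ((ci - 1L) %% nc) + 1L
    out[inside] <- tex$values[cbind(ri, ci)]
    return(out)
  }
  r0 <- floor(r)
  c0 <- floor(cl)
  fr <- r - r0
  fc <- cl - c0
  clampr <- function(i) pmin(nr, pmax(1L, i))
  wrapc <- if (wraps) {
    function(i) ((as.integer(i) - 1L) %% nc) + 1L
  } else {
    function(i) pmin(nc, pmax(1L, i))
  }
  v <- tex$values
  out[inside] <-
    v[cbind(clampr(r0), wrapc(c0))] * (1 - fr) * (1 - fc) +
    v[cbind(clampr(r0 + 1), wrapc(c0))] * fr * (1 - fc) +
    v[cbind(clampr(r0), wrapc(c0 + 1))] * (1 - fr) * fc +
    v[cbind(clampr(r0 + 1), wrapc(c0 + 1))] * fr * fc
  out
}

#' Read and write textures or projector frames as PNG
#'
#' Grayscale PNG I/O for textures (with extents supplied on read) and for
#' plain image matrices. Requires the `png` package.
#'
#' @param tex A [spherical_texture()] or numeric matrix in `[0, 1]`.
#' @param path PNG file path.
#' @param az_range,el_range Extents to attach on read.
#' @return `write_texture_png()` returns `path` invisibly;
#'   `read_texture_png()` returns a `spherical_texture`.
#' @export
write_texture_png <- function(tex, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop_domain("PNG I/O requires the `png` package")
  }
  m <- if (inherits(tex, "spherical_texture")) tex$values else tex
  png::writePNG(m, path)
  invisible(path)
}

#' @rdname write_texture_png
#' @export
read_texture_png <- function(path, az_range = c(-180, 180),
                             el_range = c(-90, 90)) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop_domain("PNG I/O requires the `png` package")
  }
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  spherical_texture(m, az_range, el_range)
}
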