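# Fabrication exports: an SVG polyline of the 2D profile (for CAD import and
# laser cutting) and a binary STL of the surface of revolution (for 3D
# printing). Matching readers are provided so exports can be verified by
# round trip.

#' Export a screen profile as an SVG polyline
#'
#' Writes a single-polyline SVG of the profile points, scaled to physical
#' units. Coordinates are written with full double precision so the file
#' round-trips through [read_profile_svg()] without loss beyond 1e-6.
#'
#' @param profile A [screen_profile()] object.
#' @param path Output file path.
#' @param scale Multiplicative scale applied to coordinates (e.g. mm per
#'   model unit). Default 1.
#' @return `path`, invisibly.
#' @export
write_profile_svg <- function(profile, path, scale = 1) {
  stopifnot(inherits(profile, "screen_profile"))
  pts <- profile$points * scale
  # SVG y grows downward; flip so the plotted curve matches the model
  coords <- paste(sprintf("%.10g,%.10g", pts[, 1], -pts[, 2]),
                  collapse = " ")
  pad <- 0.05 * max(diff(range(pts[, 1])), diff(range(pts[, 2])), 1)
  vb <- sprintf("%.10g %.10g %.10g %.10g",
                min(pts[, 1]) - pad, min(-pts[, 2]) - pad,
                diff(range(pts[, 1])) + 2 * pad,
                diff(range(pts[, 2])) + 2 * pad)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" viewBox="%s">', vb),
    sprintf('<polyline fill="none" stroke="black" stroke-width="0.2" points="%s"/>',
            coords),
    "</svg>")
  writeLines(lines, path)
  invisible(path)
}

#' Read back a profile SVG written by [write_profile_svg()]
#'
#' @param path SVG file path.
#' @return An `n x 2` matrix of profile coordinates (model orientation,
#'   y up).
#' @export
read_profile_svg <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  m <- regmatches(txt, regexpr('points="[^"]*"', txt))
  if (length(m) == 0) stop_domain("no polyline found in ", path)
  nums <- as.numeric(strsplit(gsub('points="|"', "", m), "[ ,]+")[[1]])
  out <- matrix(nums, ncol = 2, byrow = TRUE)
  out[, 2] <- -out[, 2]
  colnames(out) <- c("x", "y")
  out
}

#' Export a screen surface as a binary STL mesh
#'
#' Standard little-endian binary STL: an 80-byte header, a triangle count,
#' and per-triangle normal plus three vertices as 32-bit floats.
#'
#' @param surface A [screen_surface()] object (or any list with `vertices`
#'   and 1-based triangle `faces`).
#' @param path Output file path.
#' @param scale Multiplicative scale applied to coordinates. Default 1.
#' @return `path`, invisibly.
#' @export
write_surface_stl <- function(surface, path, scale = 1) {
  v <- surface$vertices * scale
  f <- surface$faces
  stopifnot(is.matrix(v), ncol(v) == 3, is.matrix(f), ncol(f) == 3)
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(formatC("bowlvr surface-of-revolution mesh",
                              width = 80, flag = "-"))
  writeBin(header[1:80], con)
  writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- cc - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / ifelse(len > 0, len, 1)
  # 12 floats per triangle: normal, v1, v2, v3 — interleave row-wise
  block <- cbind(nrm, a, b, cc)
  for (i in seq_len(nrow(f))) {
    writeBin(as.numeric(block[i, ]), con, size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a binary STL file
#'
#' @param path STL file path.
#' @return A list with `vertices` (`3F x 3` matrix, one row per triangle
#'   corner in file order) and `normals` (`F x 3`).
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  tri <- matrix(0, n, 12)
  for (i in seq_len(n)) {
    tri[i, ] <- readBin(con, "numeric", 12, size = 4, endian = "little")
    invisible(readBin(con, "raw", 2))
  }
  list(normals = tri[, 1:3, drop = FALSE],
       vertices = matrix(t(tri[, 4:12]), ncol = 3, byrow = TRUE))
}
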