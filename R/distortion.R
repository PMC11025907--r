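# Perspective-distortion evaluation: faces of the compound-eye polyhedron
# are projected radially onto a flat, cylindrical or bowl-shaped screen and
# measured in the screen's own image chart, i.e. in units proportional to
# projector pixels (for a flat screen the projector is uniform in physical
# screen area; for the cylinder the idealized development is used; for the
# bowl the equidistant azimuthal projector image).

#' Screen specifications for distortion evaluation
#'
#' Define the three screen geometries an observer at the origin can face:
#' a plane perpendicular to the view axis, a vertical cylinder around the
#' observer, and the bowl-shaped surface of revolution. The screen "center"
#' (the undistorted reference direction) is the +x axis in all cases; for
#' the bowl this is its pole.
#'
#' @param distance Observer-to-screen distance of the flat screen.
#' @param radius Cylinder radius.
#' @param model A [projector_model()] defining the bowl.
#' @return An object of class `screen_spec`.
#' @export
screen_flat <- function(distance = 1) {
  stopifnot(distance > 0)
  structure(list(kind = "flat", distance = distance), class = "screen_spec")
}

#' @rdname screen_flat
#' @export
screen_cylinder <- function(radius = 1) {
  stopifnot(radius > 0)
  structure(list(kind = "cylinder", radius = radius), class = "screen_spec")
}

#' @rdname screen_flat
#' @export
screen_bowl <- function(model) {
  assert_projector_model(model)
  structure(list(kind = "bowl", model = model), class = "screen_spec")
}

#' @export
print.screen_spec <- function(x, ...) {
  cat("Screen spec:", x$kind, "\n")
  invisible(x)
}

# Radial projection of unit directions (rows of `dirs`) onto the physical
# screen surface; returns n x 3 points and a validity flag.
screen_point3d <- function(dirs, screen) {
  stopifnot(inherits(screen, "screen_spec"))
  switch(screen$kind,
    flat = {
      ok <- dirs[, 1] > 1e-9
      s <- ifelse(ok, screen$distance / dirs[, 1], NA_real_)
      list(points = dirs * s, valid = ok)
    },
    cylinder = {
      rho <- sqrt(dirs[, 1]^2 + dirs[, 2]^2)
      ok <- rho > 1e-9
      s <- ifelse(ok, screen$radius / rho, NA_real_)
      list(points = dirs * s, valid = ok)
    },
    bowl = {
      m <- screen$model
      psi <- acos(pmin(1, pmax(-1, dirs[, 1])))
      ok <- psi > 1e-9 & psi < deg2rad(175)
      s <- rep(NA_real_, nrow(dirs))
      s[ok] <- abs(m$d_proj * psi[ok] /
                     (psi[ok] * cos(psi[ok]) - pi * m$r * sin(psi[ok])))
      list(points = dirs * s, valid = ok)
    })
}

# 2D image chart of each screen (area proportional to projector pixels).
screen_chart <- function(dirs, screen) {
  switch(screen$kind,
    flat = {
      ok <- dirs[, 1] > 1e-9
      d <- screen$distance
      list(uv = cbind(u = d * dirs[, 2] / dirs[, 1],
                      v = d * dirs[, 3] / dirs[, 1]),
           valid = ok)
    },
    cylinder = {
      rho <- sqrt(dirs[, 1]^2 + dirs[, 2]^2)
      ok <- rho > 1e-9
      R <- screen$radius
      list(uv = cbind(u = R * atan2(dirs[, 2], dirs[, 1]),
                      v = R * dirs[, 3] / rho),
           valid = ok)
    },
    bowl = {
      psi <- acos(pmin(1, pmax(-1, dirs[, 1])))
      beta <- atan2(dirs[, 3], dirs[, 2])
      ok <- psi < deg2rad(175)
      list(uv = cbind(u = psi * cos(beta), v = psi * sin(beta)), valid = ok)
    })
}

# Spherical linear interpolation between consecutive polygon corners,
# `k` samples per edge (corner included once).
densify_spherical_polygon <- function(corners, k) {
  n <- nrow(corners)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    a <- corners[i, ]
    b <- corners[if (i == n) 1L else i + 1L, ]
    w <- acos(pmin(1, pmax(-1, sum(a * b))))
    t <- seq(0, 1, length.out = k + 1L)[-(k + 1L)]
    pts <- outer(sin((1 - t) * w), a) + outer(sin(t * w), b)
    out[[i]] <- normalize_rows(pts)
  }
  do.call(rbind, out)
}

# Shrink a spherical polygon toward a center direction by `factor`
# (slerp each corner toward the center; factor 1 = unchanged).
shrink_spherical_polygon <- function(corners, center, factor) {
  if (factor >= 1) return(corners)
  t(apply(corners, 1, function(p) {
    w <- acos(pmin(1, pmax(-1, sum(p * center))))
    w2 <- w * factor
    if (w < 1e-12) return(center)
    u <- (p - sum(p * center) * center)
    u <- u / sqrt(sum(u^2))
    cos(w2) * center + sin(w2) * u
  }))
}

polygon_area_2d <- function(uv) {
  n <- nrow(uv)
  j <- c(2:n, 1)
  abs(sum(uv[, 1] * uv[j, 2] - uv[j, 1] * uv[, 2])) / 2
}

#' Project the faces of a compound-eye model onto a screen
#'
#' Every face edge is densified along great circles, projected radially
#' from the observer onto the screen surface, and expressed in the screen's
#' 2D image chart (units proportional to projector pixels). Faces whose
#' centroid lies outside the field of view, or that the projection cannot
#' reach, are marked invalid; faces straddling the FOV boundary are flagged.
#'
#' @param gp A [goldberg_polyhedron()] (typically [equalize_areas()] output,
#'   rotated so a face of interest sits at the screen center; see
#'   [rotate_goldberg()]).
#' @param screen A [screen_flat()], [screen_cylinder()] or [screen_bowl()].
#' @param fov Field of view in degrees: faces with centroid farther than
#'   `fov/2` from the screen center are excluded.
#' @param edge_subdiv Samples per polygon edge.
#' @param shrink Factor in `(0, 1]` shrinking each face toward its own
#'   centroid before projection (for small-face analytic limits).
#' @return An object of class `projected_faces`: list with per-face 2D
#'   `polygons`, `ecc` (eccentricity from screen center, degrees),
#'   `solid_angle` (of the possibly shrunken source face), `valid`,
#'   `straddle` flags, and the `screen`.
#' @export
project_faces <- function(gp, screen, fov = 105, edge_subdiv = 8,
                          shrink = 1) {
  stopifnot(inherits(gp, "goldberg"), inherits(screen, "screen_spec"))
  nf <- length(gp$cells)
  cen <- normalize_rows(gp$face_centers)
  ecc <- rad2deg(acos(pmin(1, pmax(-1, cen[, 1]))))
  polys <- vector("list", nf)
  src <- vector("list", nf)
  valid <- logical(nf)
  straddle <- logical(nf)
  sa <- numeric(nf)
  for (i in seq_len(nf)) {
    corners <- gp$verts[gp$cells[[i]], , drop = FALSE]
    corners <- shrink_spherical_polygon(corners, cen[i, ], shrink)
    src[[i]] <- corners
    # source solid angle of the (possibly shrunken) face
    k <- nrow(corners)
    g <- matrix(cen[i, ], k, 3, byrow = TRUE)
    sa[i] <- sum(tri_solid_angle(g, corners,
                                 corners[c(2:k, 1), , drop = FALSE]))
    rad <- max(angular_distance(corners,
                                matrix(cen[i, ], k, 3, byrow = TRUE)))
    straddle[i] <- ecc[i] <= fov / 2 & ecc[i] + rad > fov / 2
    if (ecc[i] > fov / 2) next
    dense <- densify_spherical_polygon(corners, edge_subdiv)
    ch <- screen_chart(dense, screen)
    if (!all(ch$valid)) next
    polys[[i]] <- ch$uv
    valid[i] <- TRUE
  }
  structure(list(polygons = polys, src_corners = src, ecc = ecc,
                 solid_angle = sa, valid = valid, straddle = straddle,
                 screen = screen, face_centers = cen, fov = fov),
            class = "projected_faces")
}

#' Per-face distortion metrics of projected compound-eye faces
#'
#' For every valid projected face, computes the projected area per source
#' solid angle normalized to a reference face (the valid face closest to
#' the screen center), plus elongation and width ratios: the extent of the
#' projected polygon along/perpendicular to the radial direction from the
#' screen center, corrected for the source hexagon's own angular extents
#' along the same directions and normalized to the reference face.
#'
#' @param proj A [project_faces()] result.
#' @param reference Optional face index to normalize against; default is
#'   the valid face with the smallest eccentricity.
#' @return A data.frame with one row per valid face: `face`, `ecc`, `az`,
#'   `el`, `solid_angle`, `area_ratio`, `elongation`, `width_ratio`,
#'   `straddle`.
#' @export
distortion_metrics <- function(proj, reference = NULL) {
  stopifnot(inherits(proj, "projected_faces"))
  ids <- which(proj$valid)
  if (length(ids) == 0) stop_domain("no valid projected faces")
  if (is.null(reference)) reference <- ids[which.min(proj$ecc[ids])]
  if (!proj$valid[reference]) stop_domain("reference face is not valid")

  rows <- lapply(ids, function(i) {
    uv <- proj$polygons[[i]]
    A <- polygon_area_2d(uv)
    ctr <- colMeans(uv)
    rl <- sqrt(sum(ctr^2))
    u <- if (rl > 1e-9) ctr / rl else c(1, 0)
    w <- c(-u[2], u[1])
    L <- diff(range(uv %*% u))
    W <- diff(range(uv %*% w))
    g <- proj$face_centers[i, ]
    x <- c(1, 0, 0)
    er <- x - sum(x * g) * g
    if (sqrt(sum(er^2)) < 1e-9) {
      er <- c(0, 1, 0) - g[2] * g
    }
    er <- er / sqrt(sum(er^2))
    et <- crossp(g, er)
    # local azimuthal-equidistant chart of the source corners at g
    corners <- proj$src_corners[[i]]
    rel <- corners - (corners %*% g) %*% t(g)
    ang <- angular_distance(corners, matrix(g, nrow(corners), 3, byrow = TRUE))
    dirn <- rel / pmax(row_norms(rel), 1e-300)
    loc <- cbind(deg2rad(ang) * (dirn %*% er), deg2rad(ang) * (dirn %*% et))
    Ls <- diff(range(loc[, 1]))
    Ws <- diff(range(loc[, 2]))
    azel <- azel_from_dir(matrix(g, 1))
    data.frame(face = i, ecc = proj$ecc[i], az = azel$az, el = azel$el,
               solid_angle = proj$solid_angle[i],
               area_per_sr = A / proj$solid_angle[i],
               len_per_rad = L / Ls, wid_per_rad = W / Ws,
               straddle = proj$straddle[i])
  })
  df <- do.call(rbind, rows)
  ref <- df[df$face == reference, ]
  df$area_ratio <- df$area_per_sr / ref$area_per_sr
  df$elongation <- df$len_per_rad / ref$len_per_rad
  df$width_ratio <- df$wid_per_rad / ref$wid_per_rad
  df$area_per_sr <- df$len_per_rad <- df$wid_per_rad <- NULL
  attr(df, "reference") <- reference
  df
}

#' Rotate a compound-eye model so a hexagon sits at the screen center
#'
#' Rotates the whole polyhedron by the minimal rotation that carries the
#' hexagonal face closest to the +x axis exactly onto it, so that the
#' reference face of a distortion analysis is an undistorted central
#' hexagon.
#'
#' @param gp A [goldberg_polyhedron()].
#' @return The rotated `goldberg` object.
#' @export
orient_to_center <- function(gp) {
  cen <- normalize_rows(gp$face_centers)
  hex <- which(gp$degree == 6)
  i <- hex[which.max(cen[hex, 1])]
  azel <- azel_from_dir(cen[i, , drop = FALSE])
  rotate_goldberg(gp, rotation_between(azel$az, azel$el, 0, 0))
}

#' Physical screen area subtending a circular field of view
#'
#' Numerically integrates the physical surface area of the screen patch
#' covered by all view directions within `fov/2` of the screen center, by
#' mapping a fine polar grid of directions onto the surface and summing 3D
#' triangle areas.
#'
#' @param screen A `screen_spec`.
#' @param fov Full field-of-view cone angle in degrees.
#' @param n_psi,n_beta Integration grid resolution.
#' @return Area in squared model units.
#' @export
screen_area_for_fov <- function(screen, fov = 105, n_psi = 200,
                                n_beta = 180) {
  psi <- seq(1e-4, deg2rad(fov / 2), length.out = n_psi)
  beta <- seq(0, 2 * pi, length.out = n_beta + 1L)
  P <- outer(psi, beta, function(p, b) p)    # grid
  B <- outer(psi, beta, function(p, b) b)
  dirs <- cbind(c(cos(P)), c(sin(P) * cos(B)), c(sin(P) * sin(B)))
  sp <- screen_point3d(dirs, screen)
  pts <- sp$points
  idx <- function(i, j) (j - 1L) * n_psi + i
  i <- rep(seq_len(n_psi - 1L), times = n_beta)
  j <- rep(seq_len(n_beta), each = n_psi - 1L)
  tri_area <- function(a, b, cc) {
    e1 <- b - a; e2 <- cc - a
    n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    sqrt(rowSums(n^2)) / 2
  }
  a1 <- tri_area(pts[idx(i, j), ], pts[idx(i + 1L, j), ],
                 pts[idx(i + 1L, j + 1L), ])
  a2 <- tri_area(pts[idx(i, j), ], pts[idx(i + 1L, j + 1L), ],
                 pts[idx(i, j + 1L), ])
  sum(a1, a2, na.rm = TRUE)
}

#' Write a distortion report to CSV
#'
#' @param df A [distortion_metrics()] data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_distortion_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
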