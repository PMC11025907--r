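# Goldberg-polyhedron model of the compound eye.
#
# GP(m,n) is built as the dual of an icosahedral geodesic triangulation
# {3,5+}_(m,n). Class-I frequencies (n = 0) come from direct subdivision of
# the icosahedron; the achiral class-II case (m = n) uses the lattice
# identity (m + m*w) = (1 + w)(m + 0*w) in Eisenstein integers: start from
# the frequency-(1,1) triangulation (the pentakis dodecahedron) and
# subdivide class-I by m. Chiral cases (m != n, both nonzero) are not
# supported.

icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- normalize_rows(v)
  # faces: all mutually adjacent triples, oriented outward
  d2 <- as.matrix(stats::dist(v))^2
  edge <- d2 > 1e-9 & d2 < min(d2[d2 > 1e-9]) + 1e-9
  faces <- NULL
  for (i in 1:10) for (j in (i + 1):11) for (k in (j + 1):12) {
    if (edge[i, j] && edge[j, k] && edge[i, k]) faces <- rbind(faces, c(i, j, k))
  }
  # orient outward: (b-a) x (c-a) . centroid > 0
  for (f in seq_len(nrow(faces))) {
    a <- v[faces[f, 1], ]; b <- v[faces[f, 2], ]; cc <- v[faces[f, 3], ]
    n <- crossp(b - a, cc - a)
    if (sum(n * (a + b + cc)) < 0) faces[f, ] <- faces[f, c(1, 3, 2)]
  }
  list(vertices = v, faces = faces)
}

crossp <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# The frequency-(1,1) geodesic triangulation: the pentakis dodecahedron.
# Vertices are the 20 icosahedron face centroids (dodecahedron vertices,
# degree 6) plus the 12 icosahedron vertices (pentagon apices, degree 5);
# each dodecahedral pentagon is fanned from its apex into 5 triangles.
pentakis_dodecahedron <- function(ico) {
  v <- ico$vertices
  f <- ico$faces
  cents <- normalize_rows((v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3)
  faces <- NULL
  for (i in seq_len(nrow(v))) {
    inc <- which(apply(f, 1, function(tr) i %in% tr))
    g <- v[i, ]
    ref <- if (abs(g[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- ref - sum(ref * g) * g
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- crossp(g, e1)
    cc <- cents[inc, , drop = FALSE]
    inc <- inc[order(atan2(cc %*% e2, cc %*% e1))]
    k <- length(inc)
    faces <- rbind(faces, cbind(inc, inc[c(2:k, 1)], 20L + i))
  }
  verts <- rbind(cents, v)
  # orient all triangles outward
  for (t in seq_len(nrow(faces))) {
    a <- verts[faces[t, 1], ]; b <- verts[faces[t, 2], ]
    cc <- verts[faces[t, 3], ]
    if (sum(crossp(b - a, cc - a) * (a + b + cc)) < 0) {
      faces[t, ] <- faces[t, c(1, 3, 2)]
    }
  }
  list(vertices = verts, faces = faces)
}

# Class-I subdivision by frequency nu with global vertex welding, then
# projection onto the unit sphere.
subdivide_mesh <- function(mesh, nu) {
  if (nu == 1) {
    return(list(vertices = normalize_rows(mesh$vertices),
                faces = mesh$faces))
  }
  v <- mesh$vertices
  keymap <- new.env(hash = TRUE, parent = emptyenv())
  verts <- list()
  nverts <- 0L
  get_vertex <- function(p) {
    key <- paste(sprintf("%.9f", round(p, 9)), collapse = "|")
    id <- keymap[[key]]
    if (is.null(id)) {
      nverts <<- nverts + 1L
      verts[[nverts]] <<- p
      keymap[[key]] <- nverts
      id <- nverts
    }
    id
  }
  faces <- vector("list", nrow(mesh$faces))
  for (f in seq_len(nrow(mesh$faces))) {
    a <- v[mesh$faces[f, 1], ]; b <- v[mesh$faces[f, 2], ]
    cc <- v[mesh$faces[f, 3], ]
    # local grid ids: rows i = 0..nu, row i has nu - i + 1 points
    ids <- matrix(NA_integer_, nu + 1, nu + 1)
    for (i in 0:nu) for (j in 0:(nu - i)) {
      p <- (a * (nu - i - j) + b * i + cc * j) / nu
      ids[i + 1, j + 1] <- get_vertex(p)
    }
    tris <- list()
    for (i in 0:(nu - 1)) for (j in 0:(nu - 1 - i)) {
      tris[[length(tris) + 1L]] <-
        c(ids[i + 1, j + 1], ids[i + 2, j + 1], ids[i + 1, j + 2])
      if (j < nu - 1 - i) {
        tris[[length(tris) + 1L]] <-
          c(ids[i + 2, j + 1], ids[i + 2, j + 2], ids[i + 1, j + 2])
      }
    }
    faces[[f]] <- do.call(rbind, tris)
  }
  vv <- normalize_rows(do.call(rbind, verts))
  list(vertices = vv, faces = do.call(rbind, faces))
}

# Cyclically order the triangles incident to each triangulation vertex.
order_cells <- function(verts, faces) {
  nv <- nrow(verts)
  inc <- vector("list", nv)
  for (t in seq_len(nrow(faces))) {
    for (vi in faces[t, ]) inc[[vi]] <- c(inc[[vi]], t)
  }
  cents <- normalize_rows((verts[faces[, 1], ] + verts[faces[, 2], ] +
                             verts[faces[, 3], ]) / 3)
  cells <- vector("list", nv)
  for (i in seq_len(nv)) {
    g <- verts[i, ]
    # tangent-plane basis at g
    ref <- if (abs(g[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- ref - sum(ref * g) * g
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- crossp(g, e1)
    cc <- cents[inc[[i]], , drop = FALSE]
    ang <- atan2(cc %*% e2, cc %*% e1)
    cells[[i]] <- inc[[i]][order(ang)]
  }
  cells
}

#' Construct a Goldberg polyhedron compound-eye model
#'
#' Builds GP(m, n) -- the convex polyhedron with 12 pentagonal and
#' `10 * (m^2 + m*n + n^2) - 10` hexagonal faces -- as the dual of the
#' icosahedral geodesic triangulation of the same frequency, with all
#' vertices projected onto the unit sphere. Each face of the polyhedron
#' stands for a patch of compound-eye facets of (approximately) equal solid
#' angle; the default GP(3, 3) has 272 faces, each hexagon covering a solid
#' angle equivalent to roughly nine *Drosophila* ommatidia.
#'
#' @param m,n Goldberg indices; `m >= 1` and either `n == 0` (class I) or
#'   `n == m` (class II) are supported. Default `GP(3, 3)`.
#' @return An object of class `goldberg`: list with `face_centers`
#'   (generator directions, one per polyhedron face), `verts` (dual corner
#'   directions, one per geodesic triangle), `cells` (list of corner index
#'   cycles per face), `degree` (5 or 6 per face), and the underlying
#'   triangulation (`tri_verts`, `tri_faces`).
#' @examples
#' gp <- goldberg_polyhedron(1, 1)  # truncated icosahedron, 32 faces
#' table(gp$degree)
#' @export
goldberg_polyhedron <- function(m = 3, n = 3) {
  if (m < 1 || n < 0 || (n != 0 && n != m)) {
    stop_domain("only GP(m, 0) and GP(m, m) with m >= 1 are supported")
  }
  mesh <- icosahedron()
  if (n == m) mesh <- pentakis_dodecahedron(mesh)
  mesh <- subdivide_mesh(mesh, m)
  build_goldberg_dual(mesh$vertices, mesh$faces, c(m, n))
}

build_goldberg_dual <- function(tri_verts, tri_faces, mn) {
  cells <- order_cells(tri_verts, tri_faces)
  verts <- normalize_rows((tri_verts[tri_faces[, 1], ] +
                             tri_verts[tri_faces[, 2], ] +
                             tri_verts[tri_faces[, 3], ]) / 3)
  obj <- list(face_centers = tri_verts, verts = verts, cells = cells,
              degree = lengths(cells), tri_verts = tri_verts,
              tri_faces = tri_faces, mn = mn)
  class(obj) <- "goldberg"
  obj
}

#' @export
print.goldberg <- function(x, ...) {
  sa <- face_solid_angles(x)
  hex <- x$degree == 6
  cat(sprintf("Goldberg polyhedron GP(%d,%d)\n", x$mn[1], x$mn[2]))
  cat(sprintf("  faces: %d (%d hexagons, %d pentagons); vertices: %d; edges: %d\n",
              length(x$cells), sum(hex), sum(!hex), nrow(x$verts),
              goldberg_edge_count(x)))
  cat(sprintf("  hexagon solid-angle spread: %+.2f%% / %+.2f%% about the mean\n",
              100 * (min(sa[hex]) / mean(sa[hex]) - 1),
              100 * (max(sa[hex]) / mean(sa[hex]) - 1)))
  invisible(x)
}

goldberg_edge_count <- function(gp) sum(gp$degree) / 2L

# Signed solid angle of the spherical triangle (v1, v2, v3), vectorized over
# rows (van Oosterom & Strackee).
tri_solid_angle <- function(v1, v2, v3) {
  num <- v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) +
    v1[, 2] * (v2[, 3] * v3[, 1] - v2[, 1] * v3[, 3]) +
    v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
  den <- 1 + rowSums(v1 * v2) + rowSums(v2 * v3) + rowSums(v1 * v3)
  2 * atan2(num, den)
}

#' Solid angles of all faces of a Goldberg polyhedron
#'
#' Each face is the spherical polygon spanned by its (unit) corner
#' directions; its solid angle is accumulated from the fan of spherical
#' triangles around the face's generator direction. The face solid angles
#' partition the sphere: they sum to `4 * pi`.
#'
#' @param gp A [goldberg_polyhedron()].
#' @return Numeric vector of solid angles in steradians, one per face.
#' @export
face_solid_angles <- function(gp, verts = gp$verts) {
  fan <- cell_fan_index(gp)
  g <- gp$face_centers[fan$cell, , drop = FALSE]
  sa <- tri_solid_angle(g, verts[fan$a, , drop = FALSE],
                        verts[fan$b, , drop = FALSE])
  as.numeric(rowsum(sa, fan$cell))
}

# Precompute fan triangle indices (cell id, corner a, corner b) for all
# cells; cached on the object environment-free way via attribute.
cell_fan_index <- function(gp) {
  f <- attr(gp, "fan_index", exact = TRUE)
  if (!is.null(f)) return(f)
  k <- lengths(gp$cells)
  cell <- rep(seq_along(gp$cells), k)
  a <- unlist(gp$cells, use.names = FALSE)
  b <- unlist(lapply(gp$cells, function(x) c(x[-1], x[1])), use.names = FALSE)
  list(cell = cell, a = a, b = b)
}

# The 120 orthogonal maps (rotations and reflections) of the icosahedral
# symmetry group, constructed by mapping a reference face frame onto every
# face in all vertex orders.
icosahedral_group <- function() {
  ico <- icosahedron()
  v <- ico$vertices
  fr <- lapply(seq_len(20), function(f) {
    cbind(v[ico$faces[f, 1], ], v[ico$faces[f, 2], ], v[ico$faces[f, 3], ])
  })
  b1i <- solve(fr[[1]])
  perms <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2),
                c(1, 3, 2), c(3, 2, 1), c(2, 1, 3))
  G <- list()
  for (f in seq_len(20)) for (p in perms) {
    G[[length(G) + 1L]] <- fr[[f]][, p] %*% b1i
  }
  key <- vapply(G, function(O) paste(sprintf("%.6f", O), collapse = ","),
                character(1))
  G[!duplicated(key)]
}

#' Relax a Goldberg polyhedron toward equal hexagon areas
#'
#' Adjusts the face generators on the sphere until all hexagon solid angles
#' agree with their mean to within `tol`. The generators fall into orbits of
#' the icosahedral symmetry group; orbits pinned on symmetry axes are fixed,
#' and the optimization moves only one representative per free orbit (the
#' rest follow by symmetry), so the result is exactly icosahedrally
#' symmetric and the topology is untouched. The residual spread is driven
#' far below `tol` for the supported frequencies; non-convergence raises an
#' error reporting the spread that was achieved.
#'
#' @param gp A [goldberg_polyhedron()].
#' @param tol Allowed fractional spread of hexagon solid angles about their
#'   mean (default 0.01, i.e. +/-1%).
#' @param max_iter Iteration cap for the optimizer.
#' @return A `goldberg` object whose hexagon solid angles are within
#'   `+/- tol` of their mean, with attribute `"hex_spread"`.
#' @export
equalize_areas <- function(gp, tol = 0.01, max_iter = 500) {
  stopifnot(inherits(gp, "goldberg"))
  hex <- gp$degree == 6
  V <- gp$tri_verts
  f <- gp$tri_faces
  nv <- nrow(V)
  G <- icosahedral_group()
  Gstack <- do.call(rbind, G)                      # (3*|G|) x 3
  ng <- length(G)
  # orbit decomposition of the generators
  orbit <- rep(NA_integer_, nv)
  oid <- 0L
  for (i in seq_len(nv)) {
    if (!is.na(orbit[i])) next
    oid <- oid + 1L
    imgs <- t(matrix(Gstack %*% V[i, ], 3, ng))
    orbit[unique(max.col(imgs %*% t(V)))] <- oid
  }
  reps <- vapply(split(seq_len(nv), orbit), `[`, integer(1), 1)
  osize <- as.integer(table(orbit))
  # orbits of size |G| (generic, 2 dof) or |G|/2 (on a mirror plane, 1 dof)
  # are movable; smaller orbits sit on symmetry axes and are pinned
  free <- which(osize >= ng / 2)
  spread_of <- function(Vc) {
    gp$tri_verts <- Vc
    gp$face_centers <- Vc
    verts <- normalize_rows((Vc[f[, 1], ] + Vc[f[, 2], ] + Vc[f[, 3], ]) / 3)
    sa <- face_solid_angles(gp, verts)
    sa[hex] / mean(sa[hex]) - 1
  }
  if (length(free) > 0) {
    vid <- lapply(free, function(o) {
      imgs <- t(matrix(Gstack %*% V[reps[o], ], 3, ng))
      max.col(imgs %*% t(V))
    })
    basis <- lapply(free, function(o) {
      r <- V[reps[o], ]
      ref <- if (abs(r[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- ref - sum(ref * r) * r
      e1 <- e1 / sqrt(sum(e1^2))
      list(r = r, e1 = e1, e2 = crossp(r, e1))
    })
    build <- function(par) {
      Vout <- V
      for (k in seq_along(free)) {
        b <- basis[[k]]
        x <- b$r + par[2 * k - 1] * b$e1 + par[2 * k] * b$e2
        x <- x / sqrt(sum(x^2))
        acc <- rowsum(t(matrix(Gstack %*% x, 3, ng)), vid[[k]])
        Vout[as.integer(rownames(acc)), ] <- acc / sqrt(rowSums(acc^2))
      }
      Vout
    }
    obj <- function(par) mean(spread_of(build(par))^2)
    opt <- stats::optim(rep(0, 2 * length(free)), obj, method = "BFGS",
                        control = list(maxit = max_iter, reltol = 1e-14))
    V <- build(opt$par)
  }
  dev <- spread_of(V)
  if (max(abs(dev)) > tol) {
    stop_domain(sprintf(
      "equal-area relaxation did not reach +/-%.2g%%; achieved +/-%.3g%%",
      100 * tol, 100 * max(abs(dev))))
  }
  out <- build_goldberg_dual(V, f, gp$mn)
  attr(out, "hex_spread") <- max(abs(dev))
  out
}

#' Rotate a Goldberg polyhedron
#'
#' Applies a 3x3 rotation matrix to every direction of the model (generators,
#' dual corners, triangulation).
#'
#' @param gp A [goldberg_polyhedron()].
#' @param R A 3x3 rotation matrix (e.g. from [rotation_between()]).
#' @return The rotated `goldberg` object.
#' @export
rotate_goldberg <- function(gp, R) {
  stopifnot(inherits(gp, "goldberg"), is.matrix(R), all(dim(R) == c(3, 3)))
  gp$face_centers <- gp$face_centers %*% t(R)
  gp$verts <- gp$verts %*% t(R)
  gp$tri_verts <- gp$tri_verts %*% t(R)
  gp
}

#' Export a Goldberg polyhedron as a Wavefront OBJ file
#'
#' @param gp A [goldberg_polyhedron()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_goldberg_obj <- function(gp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# bowlvr Goldberg polyhedron", con)
  writeLines(sprintf("v %.9g %.9g %.9g", gp$verts[, 1], gp$verts[, 2],
                     gp$verts[, 3]), con)
  writeLines(vapply(gp$cells, function(cl) paste("f", paste(cl, collapse = " ")),
                    character(1)), con)
  invisible(path)
}
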