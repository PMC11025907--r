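test_that("facet viewing ray is the unit vector at the elevation angle", {
  expect_equal(fly_ray(pi / 2), c(x = 0, y = 1))
  expect_equal(fly_ray(1e-9), c(x = 1, y = 0), tolerance = 1e-8)
  alphas <- seq(0.01, pi - 0.01, length.out = 50)
  expect_true(all(abs(sqrt(rowSums(fly_ray(alphas)^2)) - 1) < 1e-12))
  expect_error(fly_ray(0), "inside")
  expect_error(fly_ray(pi), "inside")
})

test_that("projector ray leaves the projector with slope alpha/(pi r)", {
  pm <- default_model()
  l0 <- projector_ray_line(0, pm)
  expect_equal(l0$point, c(100, 0))
  expect_equal(l0$direction[2], 0)
  l1 <- projector_ray_line(pi * pm$r, pm)
  expect_equal(l1$direction[2] / l1$direction[1], 1)
  slopes <- sapply(seq(0.1, 2, by = 0.1),
                   function(a) projector_ray_line(a, pm)$direction[2])
  expect_true(all(diff(slopes) > 0))
})

test_that("closed-form profile point equals the brute-force intersection", {
  set.seed(101)
  for (i in 1:200) {
    d <- runif(1, 1, 500)
    m <- projector_model(d, runif(1, 0.8, 3), runif(1, 1, 2.5))
    a <- runif(1, 0.05, pi - 0.05)
    if (abs(a * cos(a) - pi * m$r * sin(a)) < 1e-3) next
    p <- profile_point(a, m)
    o <- intersect_rays_oracle(a, m)
    expect_lt(max(abs(p - o)) / max(1, sqrt(sum(o^2))), 1e-9)
    # collinearity with the viewing direction through the origin
    f <- fly_ray(a)
    expect_lt(abs(p[1] * f[2] - p[2] * f[1]), 1e-9 * sqrt(sum(p^2)))
  }
})

test_that("profile point at pi/2 equals the analytic limit", {
  pm <- default_model()
  lim <- c(0, -pm$d_proj / (2 * pm$r))
  expect_equal(unname(profile_point(pi / 2, pm)), lim, tolerance = 1e-9)
  # numeric continuation from both sides
  expect_equal(unname(profile_point(pi / 2 - 1e-6, pm)), lim,
               tolerance = 1e-5)
  expect_equal(unname(profile_point(pi / 2 + 1e-6, pm)), lim,
               tolerance = 1e-5)
})

test_that("profile point near zero approaches d/(1 - pi r) on the x axis", {
  pm <- default_model()
  p <- profile_point(1e-7, pm)
  expect_equal(p[["x"]], pm$d_proj / (1 - pi * pm$r), tolerance = 1e-6)
  expect_lt(p[["x"]], 0)  # screen on the side opposite the projector
  expect_equal(p[["y"]], 0, tolerance = 1e-4)
})

test_that("a denominator root inside the range is refused", {
  # pi * r < 1 puts a genuine singularity below 90 degrees
  m <- projector_model(10, throw_ratio = 0.2, aspect_ratio = 1)
  expect_error(screen_profile(m, c(5, 85), n = 50), "sign")
  a_sing <- uniroot(function(a) a * cos(a) - pi * m$r * sin(a),
                    c(0.5, 1.5), tol = 1e-14)$root
  expect_error(profile_point(a_sing, m), "singular")
})

test_that("sampled profile hits endpoints, increases, and converges", {
  pm <- default_model()
  pr <- screen_profile(pm, c(15, 140), n = 100)
  expect_equal(length(pr$alpha), 100)
  expect_equal(range(pr$alpha) * 180 / pi, c(15, 140))
  expect_true(all(diff(pr$alpha) > 0))
  for (i in seq(1, 100, by = 7)) {
    o <- intersect_rays_oracle(pr$alpha[i], pm)
    expect_lt(max(abs(pr$points[i, ] - o)), 1e-9 * max(1, sqrt(sum(o^2))))
  }
  # polyline discretization error (chord midpoint vs true curve) shrinks
  # ~4x when the sampling is doubled
  chord_err <- function(n) {
    p <- screen_profile(pm, c(15, 140), n = n)
    mid_a <- (p$alpha[-1] + p$alpha[-n]) / 2
    chord_mid <- (p$points[-1, ] + p$points[-n, ]) / 2
    max(sqrt(rowSums((chord_mid - profile_point(mid_a, pm))^2)))
  }
  expect_lt(chord_err(101), chord_err(51) / 3)
})

test_that("surface of revolution embeds the profile and is symmetric", {
  pm <- default_model()
  a <- 0.8
  s0 <- surface_point(a, 0, pm)
  expect_equal(unname(s0[1:2]), unname(profile_point(a, pm)))
  expect_equal(s0[["z"]], 0)
  # distance from the rotation (x) axis is independent of beta
  betas <- seq(0, 2 * pi, length.out = 9)
  pts <- surface_point(rep(a, 9), betas, pm)
  expect_equal(diff(range(sqrt(pts[, 2]^2 + pts[, 3]^2))), 0,
               tolerance = 1e-12)
  # beta and beta + pi are mirror images through the axis
  p1 <- surface_point(a, 0.7, pm)
  p2 <- surface_point(a, 0.7 + pi, pm)
  expect_equal(p1[["x"]], p2[["x"]])
  expect_equal(p1[["y"]], -p2[["y"]])
  expect_equal(p1[["z"]], -p2[["z"]])
})

test_that("SVG profile export round-trips", {
  pm <- default_model()
  pr <- screen_profile(pm, n = 100)
  f <- withr::local_tempfile(fileext = ".svg")
  write_profile_svg(pr, f)
  back <- read_profile_svg(f)
  expect_equal(nrow(back), 100)
  expect_lt(max(abs(back - pr$points)), 1e-6)
})

test_that("STL surface export has the contracted triangle count", {
  pm <- default_model()
  su <- screen_surface(pm, n_alpha = 100, n_beta = 90)
  expect_equal(nrow(su$faces), 2 * 99 * 89)
  f <- withr::local_tempfile(fileext = ".stl")
  write_surface_stl(su, f)
  mesh <- read_stl(f)
  expect_equal(nrow(mesh$normals), 2 * 99 * 89)
  # round trip at float32 precision
  expect_lt(max(abs(mesh$vertices - su$vertices[t(su$faces), ])), 1e-4)
  # no degenerate triangles
  a <- mesh$vertices[seq(1, nrow(mesh$vertices), 3), ]
  b <- mesh$vertices[seq(2, nrow(mesh$vertices), 3), ]
  cc <- mesh$vertices[seq(3, nrow(mesh$vertices), 3), ]
  cr <- cbind((b - a)[, 2] * (cc - a)[, 3] - (b - a)[, 3] * (cc - a)[, 2],
              (b - a)[, 3] * (cc - a)[, 1] - (b - a)[, 1] * (cc - a)[, 3],
              (b - a)[, 1] * (cc - a)[, 2] - (b - a)[, 2] * (cc - a)[, 1])
  expect_true(all(sqrt(rowSums(cr^2)) / 2 > 1e-6))
})
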