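test_that("equidistant azimuthal projection is linear in the polar angle", {
  pm <- default_model()
  expect_equal(eqaz_forward(0, 0, pm)$radius_px, 0)
  full <- eqaz_forward(180, 0, pm)$radius_px
  expect_equal(eqaz_forward(90, 0, pm)$radius_px, full / 2)
  # bijection on the domain
  a <- seq(1, 179, by = 7)
  b <- seq(-170, 170, length.out = length(a))
  f <- eqaz_forward(a, b, pm)
  inv <- eqaz_inverse(f$radius_px, f$angle_deg, pm)
  expect_equal(inv$alpha, a, tolerance = 1e-12)
  expect_equal(inv$beta, b, tolerance = 1e-12)
  expect_true(all(eqaz_forward(c(150, 170), 0, pm, alpha_max = 140)$off_screen))
})

test_that("pixel maps are geometry-only and respect the mask", {
  pm <- default_model()
  maps <- build_pixel_maps(pm)
  const <- spherical_texture(matrix(0.7, 125, 180), c(-90, 90), c(-75, 50))
  img <- apply_maps(const, maps)
  expect_true(all(img[maps$valid] == 0.7))
  expect_true(all(img[!maps$valid] == 0))
  # all-zero texture stays black
  zero <- spherical_texture(matrix(0, 125, 180), c(-90, 90), c(-75, 50))
  expect_true(all(apply_maps(zero, maps) == 0))
  # a texture that cannot cover the FOV is refused
  expect_error(build_pixel_maps(pm, texture_dims = c(50, 60),
                                az_range = c(-30, 30),
                                el_range = c(-20, 20)),
               "cover")
})

test_that("a single lit texel round-trips through the maps", {
  pm <- default_model()
  maps <- build_pixel_maps(pm)
  tex <- spherical_texture(matrix(0, 125, 180), c(-90, 90), c(-75, 50))
  tex$values[60, 95] <- 1
  img <- apply_maps(tex, maps)
  lit <- which(img > 0, arr.ind = TRUE)
  expect_gt(nrow(lit), 0)
  back_r <- maps$map_row[lit]
  back_c <- maps$map_col[lit]
  expect_true(all(abs(back_r - 60) <= 1))
  expect_true(all(abs(back_c - 95) <= 1))
})

test_that("map lookup is linear in the texture", {
  pm <- default_model()
  maps <- build_pixel_maps(pm)
  t1 <- smooth_screen_texture(1)
  t2 <- smooth_screen_texture(2)
  mix <- spherical_texture(0.3 * t1$values + 0.6 * t2$values,
                           c(-90, 90), c(-75, 50))
  expect_equal(apply_maps(mix, maps),
               0.3 * apply_maps(t1, maps) + 0.6 * apply_maps(t2, maps),
               tolerance = 1e-12)
})

test_that("identity rotation reproduces the texture exactly", {
  tex <- smooth_screen_texture(7)
  rot <- rotate_equirect(tex, diag(3))
  expect_equal(rot$values, tex$values, tolerance = 1e-9)
})

test_that("rotation recenters a delta to the map center", {
  tex <- spherical_texture(matrix(0, 180, 360), c(-180, 180), c(-90, 90))
  ix <- bowlvr:::texture_index(tex, 50, 20)
  tex$values[round(ix$row), round(ix$col)] <- 1
  rot <- rotate_equirect(tex, rotation_between(50, 20, 0, 0))
  pk <- which(rot$values == max(rot$values), arr.ind = TRUE)[1, ]
  ctr <- bowlvr:::texture_index(tex, 0, 0)
  expect_lte(abs(pk[1] - ctr$row), 1)
  expect_lte(abs(pk[2] - ctr$col), 1)
})

test_that("composed rotations match the composite rotation", {
  tex0 <- smooth_screen_texture(9)
  # embed in a full-sphere texture so nothing rotates off the map
  full <- spherical_texture(matrix(0.5, 180, 360), c(-180, 180), c(-90, 90))
  full$values[41:165, 91:270] <- tex0$values
  set.seed(31)
  for (i in 1:3) {
    R1 <- rotation_axis_angle(rnorm(3), runif(1, 5, 25))
    R2 <- rotation_axis_angle(rnorm(3), runif(1, 5, 25))
    seq2 <- rotate_equirect(rotate_equirect(full, R1), R2)
    onego <- rotate_equirect(full, R2 %*% R1)
    expect_lt(mean(abs(seq2$values - onego$values)), 0.01)
  }
})

test_that("rotation conserves image mass on smooth full-sphere textures", {
  g <- stats::setNames(expand.grid(el = seq(89.5, -89.5, by = -1),
                                   az = seq(-179.5, 179.5, by = 1)),
                       c("el", "az"))
  vals <- matrix(0.5 + 0.3 * sin(3 * g$az * pi / 180) *
                   cos(2 * g$el * pi / 180), 180, 360)
  tex <- spherical_texture(vals, c(-180, 180), c(-90, 90))
  mass <- function(t) {
    el <- seq(89.5, -89.5, by = -1)
    sum(t$values * cos(el * pi / 180))
  }
  rot <- rotate_equirect(tex, rotation_axis_angle(c(0.3, 1, 0.5), 33))
  expect_equal(mass(rot), mass(tex), tolerance = 0.02)
})

test_that("texture to projector to camera round trip is faithful", {
  pm <- default_model()
  maps <- build_pixel_maps(pm)
  tex <- smooth_screen_texture(42)
  cap <- camera_capture(apply_maps(tex, maps), maps, out_dims = c(125, 180))
  on <- attr(cap, "on_screen")
  expect_gte(cor(tex$values[on], cap$values[on]), 0.95)
  expect_lte(mean(abs(tex$values[on] - cap$values[on])), 0.05)
})
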