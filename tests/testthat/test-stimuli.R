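test_that("cylinder grating wraps with the exact cycle count", {
  tex <- cylinder_grating(period = 30, height = 36, res = 1)
  row <- tex$values[round(bowlvr:::texture_index(tex, 0, -10)$row), ]
  # 12 cycles -> 24 sign changes of the centered wave around the circle
  flips <- sum(diff(sign(c(row, row[1]) - 0.5)) != 0)
  expect_equal(flips, 24)
  # textured band spans the horizon down to -36 degrees
  el <- bowlvr:::texture_el(tex)
  contrast_rows <- apply(tex$values, 1, function(r) diff(range(r)) > 0)
  expect_true(all(el[contrast_rows] >= -36 & el[contrast_rows] <= 0))
  expect_true(any(contrast_rows))
  # full-contrast square wave averages to mid gray
  expect_equal(mean(tex$values[contrast_rows, ]), 0.5, tolerance = 30 / 720)
  expect_error(cylinder_grating(period = 25), "divide")
})

test_that("moving edge follows the kinematics and polarity", {
  e0 <- moving_edge("bright", velocity = 60, t = 0, start = -90)
  az <- bowlvr:::texture_az(e0)
  row0 <- e0$values[50, ]
  expect_equal(max(az[row0 == 1]), -90, tolerance = 1)
  e1 <- moving_edge("bright", velocity = 60, t = 1, start = -90)
  expect_equal(max(az[e1$values[50, ] == 1]), -30, tolerance = 1)
  d1 <- moving_edge("dark", velocity = 60, t = 1, start = -90)
  expect_equal(d1$values, 1 - e1$values)
})

test_that("dark bar has the right span, fraction and wraparound", {
  b <- dark_bar(width = 15, position = 0)
  az <- bowlvr:::texture_az(b)
  darkcols <- b$values[1, ] == 0
  expect_true(all(abs(az[darkcols]) <= 7.5))
  expect_lt(abs(mean(b$values == 0) - 15 / 360), 2 / 360)
  expect_equal(dark_bar(width = 15, position = 30)$values,
               dark_bar(width = 15, position = 390)$values)
  # wrap-safe across the 180/-180 seam
  seam <- dark_bar(width = 20, position = 180)
  expect_lt(abs(mean(seam$values == 0) - 20 / 360), 2 / 360)
})

test_that("cuboid interior has four graded edges at the stated luminances", {
  # fine grid: pixel centers sit within res/2 of the edge azimuths, so the
  # sampled dip centers agree with the nominal luminances to second order
  tex <- cuboid_interior(res = 0.2)
  prof <- tex$values[1, ]
  az <- bowlvr:::texture_az(tex)
  at <- function(a) prof[which.min(abs(wrap_angle_diff(az, a)))]
  expect_lt(abs(at(0) - 0.67), 1e-4)
  expect_lt(abs(at(90) - 0.77), 1e-4)
  expect_lt(abs(at(180) - 0.67), 1e-4)
  expect_lt(abs(at(270) - 0.77), 1e-4)
  expect_equal(at(45), 0.98, tolerance = 1e-9)
  expect_equal(max(prof), 0.98, tolerance = 1e-9)
  # exactly four luminance dips around the circle
  below <- prof < 0.9
  expect_equal(sum(diff(c(below[length(below)], below)) == 1), 4)
  # a 90-degree yaw advances the edge labels by one
  rot <- cuboid_interior(yaw = 90, res = 0.2)
  expect_equal(rot$values[1, ],
               cuboid_interior(edge_lums = c(0.77, 0.67, 0.77, 0.67),
                               res = 0.2)$values[1, ],
               tolerance = 1e-12)
})

test_that("noise grid dimensions follow the cell size", {
  g <- noise_grid(cell = 5, az_extent = 180, el_extent = 140)
  expect_equal(g$az_bins, 36L)
  expect_equal(g$el_bins, 28L)
  expect_error(noise_grid(cell = 7), "divide")
})

test_that("noise frames are Bernoulli(1/2), seeded, and addressable", {
  g <- noise_grid(seed = 99)
  s1 <- binary_noise(g, 30)
  s2 <- binary_noise(g, 30)
  expect_identical(s1$frames, s2$frames)
  expect_true(all(s1$frames %in% c(0, 1)))
  # out-of-order frame addressing matches the sequence
  expect_equal(as.vector(noise_frame(g, 17)), s1$frames[17, ])
  expect_equal(as.vector(noise_frame(g, 3)), s1$frames[3, ])
  # global mean within a 3-sigma binomial bound
  n <- length(s1$frames)
  expect_lt(abs(mean(s1$frames) - 0.5), 3 * 0.5 / sqrt(n))
  # different seeds decorrelate
  g2 <- noise_grid(seed = 100)
  expect_false(identical(binary_noise(g2, 1)$frames, s1$frames[1:60, ]))
})

test_that("noise has delta-like spatial and temporal autocorrelation", {
  g <- noise_grid(seed = 5)
  s <- binary_noise(g, 120)
  x <- 2 * s$frames - 1
  n <- s$n_frames
  bound <- 3 / sqrt(n)
  # temporal: a few pixels, lags 1..3
  for (px in c(1, 500, 1008)) {
    for (lag in 1:3) {
      r <- mean(x[seq_len(n - lag), px] * x[seq_len(n - lag) + lag, px])
      expect_lt(abs(r), bound)
    }
  }
  # spatial: neighboring cells
  bound_s <- 3 / sqrt(n)
  expect_lt(abs(mean(rowMeans(x[, 1:10] * x[, 2:11]))), bound_s)
})

test_that("trial scheduling is frame-accurate and reproducible", {
  tl <- trial_timeline()
  expect_equal(tl$total_s, 14)
  fr <- trial_frames(tl, "cw", velocity = 60, rate = 60)
  expect_equal(nrow(fr), 840)
  expect_equal(which(fr$phase == "stimulation")[1], 121)
  expect_equal(which(fr$phase == "post")[1], 481)
  # cw at 60 deg/s advances 1 degree per frame at 60 Hz
  stim <- fr$phase == "stimulation"
  expect_equal(unique(round(diff(fr$yaw[stim]), 12)), 1)
  # static phases render identical frames
  fs <- trial_frames(tl, "static")
  expect_true(all(fs$yaw == 0))
  conds <- data.frame(direction = c("cw", "ccw", "static"))
  s1 <- schedule_trials(tl, conds, function(yaw) dark_bar(position = yaw),
                        seed = 4)
  s2 <- schedule_trials(tl, conds, function(yaw) dark_bar(position = yaw),
                        seed = 4)
  expect_identical(s1$order, s2$order)
  t1 <- s1$frame_texture(1, 200)
  expect_s3_class(t1, "spherical_texture")
})
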