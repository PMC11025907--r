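test_that("photodiode is linear with the configured gain and latency", {
  g <- noise_grid(seed = 3)
  stim <- binary_noise(g, 2)
  pd <- photodiode_model(gain = 2.5)
  # full-bright frames -> constant response equal to the gain
  bright <- stim
  bright$frames[] <- 1
  r <- photodiode_respond(bright, pd)
  expect_true(all(r$samples == 2.5))
  # linearity in luminance
  half <- stim
  half$frames <- 0.5 * stim$frames
  expect_equal(photodiode_respond(half, pd)$samples,
               0.5 * photodiode_respond(stim, pd)$samples,
               tolerance = 1e-12)
  # latency shifts the drive by whole frames
  pdl <- photodiode_model(latency = 3 / 60)
  r0 <- photodiode_respond(stim, photodiode_model())
  rl <- photodiode_respond(stim, pdl)
  expect_equal(rl$samples[4:120], r0$samples[1:117])
  expect_error(photodiode_respond(stim, photodiode_model(
    az_window = c(200, 210), el_window = c(0, 10))), "outside")
})

test_that("zero-latency photodiode kernel support stays within 3 frames", {
  g <- noise_grid(seed = 12)
  stim <- binary_noise(g, 120)
  pd <- photodiode_model(noise_sd = 0.02)
  k <- reverse_correlate(stim, photodiode_respond(stim, pd, seed = 2), 20)
  expect_lte(kernel_temporal_support(k), 3)
  expect_equal(kernel_peak_lag(k), 0L)
})

test_that("LN neuron responds as its nonlinearity dictates", {
  g <- noise_grid(seed = 4)
  stim <- binary_noise(g, 2)
  nm <- ln_neuron_model(center = c(0, -20), offset = -1)
  # zero-contrast stimulus -> constant response at the nonlinearity of 0
  gray <- stim
  gray$frames[] <- 0.5
  r <- neuron_respond(gray, nm)
  expect_true(all(abs(r$samples - (-1)) < 1e-12))
  expect_error(neuron_respond(stim, ln_neuron_model(center = c(120, 0))),
               "outside")
})

test_that("flipping the spatial polarity flips the recovered kernel", {
  g <- noise_grid(seed = 14)
  stim <- binary_noise(g, 90)
  k_off <- reverse_correlate(
    stim, neuron_respond(stim, ln_neuron_model(center = c(0, -20),
                                               polarity = -1)), 10)
  k_on <- reverse_correlate(
    stim, neuron_respond(stim, ln_neuron_model(center = c(0, -20),
                                               polarity = 1)), 10)
  pk <- bowlvr:::strf_peak(k_off)
  expect_equal(pk$sign, -1)
  expect_equal(bowlvr:::strf_peak(k_on)$sign, 1)
  expect_lt(cor(c(k_off$values[1:6, , ]), c(k_on$values[1:6, , ])), -0.9)
})

test_that("reverse correlation recovers the neuron's receptive-field center", {
  g <- noise_grid(seed = 15)
  stim <- binary_noise(g, 150)
  nm <- ln_neuron_model(center = c(22, -33), noise_sd = 0.05)
  k <- reverse_correlate(stim, neuron_respond(stim, nm, seed = 6), 20)
  ctr <- rf_center(k)
  expect_lt(abs(ctr[1] - 22), g$cell)
  expect_lt(abs(ctr[2] + 33), g$cell)
})

test_that("the virtual camera is constant and monotone in luminance", {
  pm <- default_model()
  maps <- build_pixel_maps(pm)
  img <- matrix(0.4, 720, 1280)
  img[!maps$valid] <- 0
  cap <- camera_capture(img, maps, out_dims = c(125, 180))
  on <- attr(cap, "on_screen")
  expect_true(all(cap$values[on] == 0.4))
  cap2 <- camera_capture(pmin(img * 2, 1), maps, out_dims = c(125, 180))
  expect_true(all(cap2$values[on] >= cap$values[on]))
  # optional shading field attenuates multiplicatively
  sh <- matrix(0.8, 125, 180)
  cap3 <- camera_capture(img, maps, out_dims = c(125, 180), shading = sh)
  expect_equal(cap3$values[on], 0.8 * cap$values[on], tolerance = 1e-12)
})

test_that("wingbeat image generator is symmetric, monotone and seeded", {
  img_eq <- wingbeat_image(70, 70, dims = c(200, 240))
  expect_equal(img_eq, img_eq[, ncol(img_eq):1], tolerance = 1e-12)
  m <- wingbeat_masks(c(200, 240))
  means <- sapply(c(40, 55, 70, 85), function(a) {
    mean(wingbeat_image(a, 60, dims = c(200, 240))[m$left])
  })
  expect_true(all(diff(means) > 0))
  n1 <- wingbeat_image(70, 60, dims = c(100, 120), noise_sd = 0.05, seed = 9)
  n2 <- wingbeat_image(70, 60, dims = c(100, 120), noise_sd = 0.05, seed = 9)
  expect_identical(n1, n2)
  n3 <- wingbeat_image(70, 60, dims = c(100, 120), noise_sd = 0.05, seed = 10)
  expect_false(identical(n1, n3))
})
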