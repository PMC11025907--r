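test_that("wingbeat amplitudes are symmetric and illumination-compensated", {
  img <- wingbeat_image(70, 70, dims = c(200, 240))
  m <- wingbeat_masks(c(200, 240))
  wa <- wingbeat_amplitudes(img, m)
  expect_equal(wa[["diff"]], 0, tolerance = 1e-12)
  # doubled illumination with halved weights leaves L and R unchanged
  m2 <- wingbeat_masks(c(200, 240), weights = c(0.5, 0.5))
  wa2 <- wingbeat_amplitudes(2 * img, m2)
  expect_equal(wa2[["L"]], wa[["L"]], tolerance = 1e-12)
  expect_equal(wa2[["R"]], wa[["R"]], tolerance = 1e-12)
  # a larger left envelope reads as L > R, monotonically
  diffs <- sapply(c(50, 60, 70, 80), function(a) {
    wingbeat_amplitudes(wingbeat_image(a, 50, dims = c(200, 240)), m)[["diff"]]
  })
  expect_true(all(diff(diffs) > 0))
  expect_gt(diffs[4], 0)
  # background subtraction
  bg <- matrix(0.1, 200, 240)
  wa3 <- wingbeat_amplitudes(img + 0.1, m, background = bg)
  expect_equal(wa3[["L"]], wa[["L"]], tolerance = 1e-12)
  expect_error(wingbeat_amplitudes(img[1:10, 1:10], m), "dimensions")
})

test_that("steering preprocessing zeroes constants and matches an oracle", {
  tl <- trial_timeline()
  rate <- 120
  n <- tl$total_s * rate
  const <- steering_signal(rep(3, n), rep(1, n), rate)
  expect_equal(max(abs(process_steering(const, tl)$response)), 0)
  # independent oracle: direct O(n^2) resample + Gaussian convolution
  set.seed(77)
  L <- 5 + cumsum(rnorm(n, 0, 0.01))
  R <- 5 + cumsum(rnorm(n, 0, 0.01))
  sig <- steering_signal(L, R, rate)
  got <- process_steering(sig, tl)
  oracle_smooth <- function(x, out_rate = 50, tau = 0.4) {
    t_in <- (seq_along(x) - 1) / rate
    t_out <- seq(0, t_in[length(t_in)], by = 1 / out_rate)
    y <- approx(t_in, x, xout = t_out, rule = 2)$y
    half <- round(3 * tau * out_rate)
    ker <- exp(-((-half:half) / out_rate)^2 / (2 * tau^2))
    ker <- ker / sum(ker)
    yp <- c(rep(y[1], half), y, rep(y[length(y)], half))
    sapply(seq_along(y), function(i) sum(yp[i:(i + 2 * half)] * rev(ker)))
  }
  d <- oracle_smooth(L) - oracle_smooth(R)
  d <- d - mean(d[seq(0, length(d) - 1) / 50 < 2])
  expect_lt(max(abs(got$response - d)), 1e-9)
  expect_error(process_steering(steering_signal(1:10, 1:10, rate), tl),
               "timeline")
})

test_that("antisymmetric step responses are recovered by rectified averaging", {
  tl <- trial_timeline()
  rate <- 120
  t <- seq(0, tl$total_s - 1 / rate, by = 1 / rate)
  A <- 2
  stimwin <- t >= tl$reference_s & t < tl$reference_s + tl$stimulation_s
  cw <- steering_signal(5 + A * stimwin, rep(5, length(t)), rate)
  ccw <- steering_signal(rep(5, length(t)), 5 + A * stimwin, rate)
  resp <- optomotor_response(cw, ccw, tl)
  # rectification identity: for an exactly antisymmetric pair the rectified
  # average reproduces the common response trace exactly
  expect_equal(resp$trace$rectified, resp$trace$cw, tolerance = 1e-12)
  expect_equal(resp$trace$ccw, -resp$trace$cw, tolerance = 1e-12)
  # plateau sits at A up to the smoothing leak into the baseline window
  plateau <- resp$trace$time >= 4 & resp$trace$time <= 7
  expect_equal(mean(resp$trace$rectified[plateau]), A, tolerance = 0.1)
  expect_gt(mean(resp$trace$cw[plateau]), 0.85 * A)
  expect_lt(mean(resp$trace$ccw[plateau]), -0.85 * A)
  expect_gt(resp$scalar, 0)
})

test_that("closed-loop stepping clips, wraps and composes linearly", {
  st <- closed_loop_state(yaw = 10, gain = 100, max_rate = 140)
  expect_equal(closed_loop_step(st, 0, 0.1)$yaw, 10)
  # gain * steering = 200 deg/s -> clipped to 140
  expect_equal(closed_loop_step(st, 2, 1)$yaw, (10 + 140) %% 360)
  # two dt steps equal one 2 dt step for constant steering
  two <- closed_loop_step(closed_loop_step(st, 0.5, 0.1), 0.5, 0.1)
  one <- closed_loop_step(st, 0.5, 0.2)
  expect_equal(two$yaw, one$yaw, tolerance = 1e-12)
  # wrap
  expect_lt(closed_loop_step(closed_loop_state(359, 100, 140), 1, 1)$yaw, 360)
})

test_that("fixation density is a proper density on the circle", {
  # uniform-rate full rotations -> flat density (rotation incommensurate
  # with the bin width so samples equidistribute)
  yaw <- ((0:5999) * 1.23456789) %% 360
  d <- fixation_density(yaw, rate = 50)
  expect_equal(sum(d$density) * 3.6, 1, tolerance = 1e-9)
  expect_lt(diff(range(d$density)), 0.2 * mean(d$density))
  # stationary yaw -> all mass in one bin
  ds <- fixation_density(rep(42, 500), rate = 50)
  expect_equal(sum(ds$density > 0), 1)
  expect_equal(sum(ds$density) * 3.6, 1, tolerance = 1e-9)
  expect_error(fixation_density(numeric(1), 50), "short")
})

test_that("a dark-seeking fly prefers the darker cuboid edges", {
  tex <- cuboid_interior(res = 2)   # darker edges at texture azimuth 0, 180
  dens <- list()
  for (tr in 1:4) {
    pol <- dark_seeking_policy(k = 0.05, noise_sd = 0.6, seed = 40 + tr)
    traj <- simulate_fixation(tex, pol, duration_s = 30, rate = 60,
                              gain = 100, seed = 40 + tr)
    dens[[tr]] <- fixation_density(traj$yaw, 60)
  }
  avg <- average_fixation_density(dens)
  near <- function(centers) {
    sapply(avg$mid, function(m) {
      any(abs(bowlvr::wrap_angle_diff(m, centers)) <= 25)
    })
  }
  p_dark <- sum(avg$density[near(c(0, 180))]) * 3.6
  p_light <- sum(avg$density[near(c(90, 270))]) * 3.6
  expect_gt(p_dark, p_light)
})

test_that("syn-directional steering yields the optomotor sign pattern", {
  # a steering model that follows pattern motion: L - R proportional to
  # the yaw velocity of the displayed grating
  tl <- trial_timeline()
  rate <- 120
  make_signal <- function(direction) {
    fr <- trial_frames(tl, direction, velocity = 60, rate = rate)
    vel <- c(0, diff(fr$yaw)) * rate / 60   # normalized pattern velocity
    steering_signal(5 + 0.5 * vel, rep(5, nrow(fr)), rate)
  }
  resp <- optomotor_response(make_signal("cw"), make_signal("ccw"), tl)
  mid <- resp$trace$time >= 4 & resp$trace$time <= 7
  expect_gt(mean(resp$trace$cw[mid]), 0)
  expect_lt(mean(resp$trace$ccw[mid]), 0)
  expect_gt(resp$scalar, 0)
})
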