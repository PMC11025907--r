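test_that("optimized reverse correlation equals the naive oracle exactly", {
  set.seed(21)
  for (i in 1:20) {
    g <- noise_grid(cell = 20, az_extent = sample(c(40, 60, 80), 1),
                    el_extent = sample(c(40, 60), 1), seed = i)
    stim <- binary_noise(g, runif(1, 1, 3))
    resp <- response_trace(rnorm(stim$n_frames), g$rate)
    ml <- sample(3:6, 1)
    k <- reverse_correlate(stim, resp, ml)
    expect_lt(max(abs(k$values - reverse_correlate_naive(stim, resp, ml))),
              1e-10)
  }
})

test_that("self-correlation of one pixel yields a delta kernel", {
  g <- noise_grid(cell = 10, az_extent = 60, el_extent = 40, seed = 8)
  stim <- binary_noise(g, 120)
  px <- 11  # column-major index into the 4 x 6 grid
  resp <- response_trace(stim$frames[, px], g$rate)
  k <- reverse_correlate(stim, resp, 8)
  peak <- max(abs(k$values))
  expect_equal(which.max(abs(k$values[1, , ])), px)
  expect_equal(bowlvr:::strf_peak(k)$lag, 0L)
  off <- abs(k$values)
  off[1, (px - 1) %% 4 + 1, (px - 1) %/% 4 + 1] <- 0
  expect_lt(max(off), 5 / sqrt(stim$n_frames) * peak)
})

test_that("a constant response gives an all-zero kernel", {
  g <- noise_grid(cell = 20, az_extent = 40, el_extent = 40, seed = 9)
  stim <- binary_noise(g, 2)
  k <- reverse_correlate(stim, response_trace(rep(3.3, stim$n_frames),
                                              g$rate), 4)
  expect_equal(max(abs(k$values)), 0)
  expect_error(rf_center(k), "undefined")
})

test_that("max_lag must leave frames to sum over", {
  g <- noise_grid(cell = 20, az_extent = 40, el_extent = 40, seed = 9)
  stim <- binary_noise(g, 1)
  expect_error(reverse_correlate(stim, response_trace(rnorm(60), 60), 60),
               "max_lag")
})

gaussian_strf <- function(center = c(10, -20), fwhm = 12, res = 2,
                          amp = 1) {
  az <- -90 + (seq_len(180 / res) - 0.5) * res
  el <- 50 - (seq_len(140 / res) - 0.5) * res
  sigma <- fwhm / 2.3548
  d2 <- outer(el, az, function(e, a) {
    acos(pmin(1, cos((e - center[2]) * pi / 180) *
                cos((a - center[1]) * pi / 180))) * 180 / pi
  })
  vals <- array(0, c(3, length(el), length(az)))
  vals[2, , ] <- amp * exp(-d2^2 / (2 * sigma^2))
  bowlvr:::new_strf(vals, c(-90, 90), c(-90, 50), 60)
}

test_that("center of mass recovers a Gaussian blob and is equivariant", {
  k <- gaussian_strf(center = c(10, -20))
  expect_equal(unname(rf_center(k)), c(10, -20), tolerance = 0.2)
  # translation of the map translates the center equally
  k2 <- gaussian_strf(center = c(-14, -6))
  expect_equal(unname(rf_center(k2) - rf_center(k)), c(-24, 14),
               tolerance = 0.4)
})

test_that("recentering preserves an already-centered kernel and its mass", {
  k <- gaussian_strf(center = c(0, 0), res = 1)
  rec <- recenter_rf(k, out_res = 1)
  # compare over the common window
  st0 <- rf_stats(k, time_window = c(0.01, 0.02), baseline_lags = integer(0))
  st1 <- rf_stats(rec, time_window = c(0.01, 0.02),
                  baseline_lags = integer(0))
  expect_equal(st1$fwhm_az, st0$fwhm_az, tolerance = 0.05)
  expect_equal(st1$size_deg2, st0$size_deg2, tolerance = 0.02 * st0$size_deg2)
  # solid-angle integral of |kernel| is conserved by the resampling
  mass <- function(x) {
    d <- dim(x$values)
    daz <- diff(x$az_range) / d[3]
    del <- diff(x$el_range) / d[2]
    el <- x$el_range[2] - (seq_len(d[2]) - 0.5) * del
    sum(abs(x$values[2, , ]) * cos(el * pi / 180)) * daz * del
  }
  expect_equal(mass(rec), mass(k), tolerance = 0.02 * mass(k))
})

test_that("FWHM of a synthetic Gaussian field matches 2.355 sigma", {
  k <- gaussian_strf(center = c(0, 0), fwhm = 10, res = 1)
  st <- rf_stats(k, time_window = c(0.01, 0.02), baseline_lags = integer(0))
  expect_equal(st$fwhm_az, 10, tolerance = 1)
  expect_equal(st$fwhm_el, 10, tolerance = 1)
  # doubling amplitude doubles the peak but not the width
  k2 <- gaussian_strf(center = c(0, 0), fwhm = 10, res = 1, amp = 2)
  st2 <- rf_stats(k2, time_window = c(0.01, 0.02),
                  baseline_lags = integer(0))
  expect_equal(st2$peak_value / st$peak_value, 2, tolerance = 1e-9)
  expect_equal(st2$fwhm_az, st$fwhm_az, tolerance = 1e-9)
})
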