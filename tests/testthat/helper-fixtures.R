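# Shared fixtures, built in code at test time.

default_model <- function(d = 100) projector_model(d_proj = d)

# Brute-force 2x2 line-line intersection of the facet viewing ray and the
# projector ray; the independent oracle for the closed-form profile point.
intersect_rays_oracle <- function(alpha, model) {
  A <- cbind(c(cos(alpha), sin(alpha)),
             -c(1, alpha / (pi * model$r)))
  s <- solve(A, c(model$d_proj, 0))
  s[1] * c(cos(alpha), sin(alpha))
}

# Band-limited texture over the screen FOV: bilinear upsampling of a coarse
# random grid (features >= 10x the texture resolution).
smooth_screen_texture <- function(seed = 42, nr = 125, nc = 180,
                                  coarse = c(13, 18)) {
  set.seed(seed)
  base <- list(values = matrix(runif(coarse[1] * coarse[2]),
                               coarse[1], coarse[2]),
               az_range = c(-90, 90), el_range = c(-75, 50))
  az <- -90 + (seq_len(nc) - 0.5) * 180 / nc
  el <- 50 - (seq_len(nr) - 0.5) * 125 / nr
  AZ <- matrix(rep(az, each = nr), nr, nc)
  EL <- matrix(rep(el, times = nc), nr, nc)
  vals <- matrix(bowlvr:::sample_texture(base, c(AZ), c(EL)), nr, nc)
  spherical_texture(vals, c(-90, 90), c(-75, 50))
}

# Naive triple-loop reverse correlation (the exactness oracle).
reverse_correlate_naive <- function(stim, response, max_lag) {
  r <- response$samples - mean(response$samples)
  S <- 2 * stim$frames - 1
  g <- stim$grid
  K <- array(0, c(max_lag + 1, g$el_bins, g$az_bins))
  for (lag in 0:max_lag) {
    for (px in seq_len(ncol(S))) {
      acc <- 0
      for (t in seq.int(lag + 1, stim$n_frames)) {
        acc <- acc + S[t - lag, px] * r[t]
      }
      K[lag + 1, (px - 1) %% g$el_bins + 1, (px - 1) %/% g$el_bins + 1] <-
        acc / (stim$n_frames - lag)
    }
  }
  K
}

# The equal-area GP(3,3) eye model is expensive enough to share across
# test files (built once per test run).
shared_eye_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- orient_to_center(equalize_areas(goldberg_polyhedron(3, 3)))
    }
    cache
  }
})
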