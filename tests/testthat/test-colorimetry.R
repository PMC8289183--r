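uniform_frame <- function(rgb, h = 4, w = 4) {
  array(rep(rgb, each = h * w), dim = c(h, w, 3))
}

test_that("red fraction averages R/(R+G+B) over pixels", {
  expect_equal(red_fraction(uniform_frame(c(255, 0, 0))), 1)
  expect_equal(red_fraction(uniform_frame(c(80, 80, 80))), 1 / 3)
  # half pure-red, half gray: pixel mean of ratios is (1 + 1/3)/2
  half <- uniform_frame(c(120, 120, 120), h = 2, w = 2)
  half[1, , ] <- rep(c(255, 0, 0), each = 2)
  expect_equal(red_fraction(half), 2 / 3)
  # channel-mean convention differs on mixed frames
  expect_equal(red_fraction(half, method = "channel_mean"),
               (2 * 255 + 2 * 120) / (2 * 255 + 6 * 120))
  expect_error(red_fraction(uniform_frame(c(0, 0, 0))), "no signal")
})

test_that("red fraction is invariant under uniform brightness scaling", {
  base <- c(200, 90, 60)
  for (a in c(0.25, 0.5, 1)) {
    expect_equal(red_fraction(uniform_frame(a * base)),
                 red_fraction(uniform_frame(base)), tolerance = 1e-12)
  }
})

test_that("progress curves normalize from start to plateau", {
  # two-level step series -> 0/1 step
  lo <- uniform_frame(c(100, 100, 100))
  hi <- uniform_frame(c(200, 50, 50))
  fs <- frame_series(0:5, c(list(lo, lo, lo), list(hi, hi, hi)))
  pc <- progress_curve(fs, plateau_k = 3)
  expect_equal(pc$normalized_progress, c(0, 0, 0, 1, 1, 1))
  # constant series has no dynamic range
  flat <- frame_series(0:3, rep(list(lo), 4))
  expect_error(progress_curve(flat), "zero dynamic range")
  expect_error(progress_curve(frame_series(0:1, list(lo, hi))), "3 frames")
})

test_that("synthetic frames round-trip through the progress extraction", {
  ramp <- function(t) t / 30
  fs <- generate_frames(ramp, timestamps = 0:30, size = c(6, 6))
  pc <- progress_curve(fs, plateau_k = 1)
  expect_lt(max(abs(pc$normalized_progress - ramp(0:30))), 0.01)
})

test_that("initial rate is the initial progress slope scaled by the gold load", {
  # exactly linear progress with slope s: rate = s * c_au_0
  curve <- tibble::tibble(t_s = seq(0, 90, by = 2),
                          normalized_progress = 0.01 * seq(0, 90, by = 2))
  expect_equal(estimate_initial_rate(curve, c_au_0 = 1.25e-4, window = 0.2),
               0.01 * 1.25e-4, tolerance = 1e-12, ignore_attr = TRUE)
  # flat curve (zero-range guard bypassed by constructing the curve
  # directly) gives zero rate
  flat <- tibble::tibble(t_s = 0:10, normalized_progress = rep(0, 11))
  expect_equal(estimate_initial_rate(flat, 1e-4), 0, ignore_attr = TRUE)
  short <- tibble::tibble(t_s = 0:4,
                          normalized_progress = c(0, 0.2, 0.5, 0.8, 1))
  expect_error(estimate_initial_rate(short, 1e-4, window = 0.05),
               "fewer than 3")
})

test_that("colorimetric initial rates agree with the kinetic model at t0", {
  st <- seed_state()
  p <- rate_parameters()
  t_grid <- seq(0, 120, by = 0.1)
  tr <- simulate_reduction(st, p, t_grid)
  pc <- tibble::tibble(t_s = t_grid,
                       normalized_progress = tr$c_reduced_M /
                         max(tr$c_reduced_M))
  # a narrow tangent window keeps the straight-line bias below 2%
  rate <- estimate_initial_rate(pc, c_au_0 = max(tr$c_reduced_M),
                                window = 0.02)
  analytic <- reduction_rate_ta(st, p) + reduction_rate_citrate(st, p)
  expect_lt(abs(rate - analytic) / analytic, 0.02)
})

test_that("log-log regression recovers reaction orders", {
  conc <- c(0.5, 1, 2, 4)
  fit <- fit_reaction_order(conc^2, conc)
  expect_equal(fit$order, 2, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_error(fit_reaction_order(1, 1), "at least 2")
  expect_error(fit_reaction_order(c(1, -2), c(1, 2)), "positive")

  # exponent recovery under 2% multiplicative noise, 20 points
  set.seed(42)
  conc <- 10^seq(-5, -3, length.out = 20)
  rates <- 3 * conc^1.1 * (1 + 0.02 * rnorm(20))
  noisy <- fit_reaction_order(rates, conc)
  expect_lt(abs(noisy$order - 1.1), 0.1)
})

test_that("the default TA rate law yields the published order 1.1", {
  p <- rate_parameters()
  base <- seed_state()
  ta_grid <- exp(seq(log(2e-5), log(2e-4), length.out = 8))
  rates <- vapply(ta_grid, function(cta) {
    st <- seed_state(c_ta = cta)
    reduction_rate_ta(st, p)
  }, numeric(1))
  fit <- fit_reaction_order(rates, ta_grid)
  expect_equal(fit$order, 1.1, tolerance = 0.01)
})
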