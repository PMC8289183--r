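test_that("channel rates follow their mass-action forms", {
  p_unit <- rate_parameters(k_ta = 1, l = 1, k_cit = 1, k_pass = 1)
  st_unit <- reaction_state(c_precursor = 1, c_ta = 1, c_cit_reactive = 1,
                            c_oh = 1)
  expect_equal(reduction_rate_ta(st_unit, p_unit), 1)
  expect_equal(reduction_rate_citrate(st_unit, p_unit), 1)
  expect_equal(passivation_rate(st_unit, p_unit), 1)

  # exhausted reactants give zero rate
  st0 <- reaction_state(c_precursor = 1e-4, c_ta = 0, c_cit_reactive = 0)
  expect_identical(reduction_rate_ta(st0, p_unit), 0)
  expect_identical(reduction_rate_citrate(st0, p_unit), 0)
  expect_identical(
    passivation_rate(st_unit, rate_parameters(k_pass = 0)), 0)

  # direct-arithmetic oracles
  p <- rate_parameters(k_ta = 2, l = 1.1)
  st <- reaction_state(c_precursor = 1e-4, c_ta = 1e-4)
  expect_equal(reduction_rate_ta(st, p), 7.96214341106994e-09,
               tolerance = 1e-12)
  p2 <- rate_parameters(k_cit = 0.5)
  st2 <- reaction_state(c_precursor = 2e-4, c_cit_reactive = 1e-3)
  expect_equal(reduction_rate_citrate(st2, p2), 1e-7, tolerance = 1e-12)
  p3 <- rate_parameters(k_pass = 3)
  st3 <- reaction_state(c_precursor = 1e-4, c_oh = 1e-7)
  expect_equal(passivation_rate(st3, p3), 3e-11, tolerance = 1e-12)
})

test_that("simulation conserves gold and the TA:Au stoichiometry along trajectories", {
  st <- seed_state()
  tr <- simulate_reduction(st, rate_parameters(), seq(0, 300, by = 2))
  total0 <- st$c_precursor + st$c_passivated + st$c_reduced
  cons <- abs(tr$c_precursor_M + tr$c_passivated_M + tr$c_reduced_M -
                total0) / total0
  expect_lt(max(cons), 1e-9)
  # TA consumed vs gold reduced via the TA route: 3/20 everywhere
  consumed_ta <- st$c_ta - tr$c_ta_M[-1]
  ratio <- consumed_ta / tr$c_reduced_ta_M[-1]
  expect_lt(max(abs(ratio - 0.15) / 0.15), 1e-6)
  # monotone depletion / formation, no negative concentrations
  expect_true(all(diff(tr$c_precursor_M) <= 0))
  expect_true(all(diff(tr$c_reduced_M) >= 0))
  expect_true(all(tr$c_precursor_M >= 0 & tr$c_ta_M >= 0))
})

test_that("zero rate coefficients freeze the state", {
  p0 <- rate_parameters(k_ta = 0, k_cit = 0, k_pass = 0)
  st <- seed_state()
  tr <- simulate_reduction(st, p0, seq(0, 50, by = 5))
  expect_true(all(tr$c_precursor_M == st$c_precursor))
  expect_true(all(tr$c_ta_M == st$c_ta))
  expect_true(all(tr$c_reduced_M == 0))
})

test_that("large TA excess reduces to the pseudo-first-order closed form", {
  # precursor far below TA so the TA level is effectively constant
  p <- rate_parameters(k_ta = 600, l = 1.1, k_cit = 0, k_pass = 0)
  st <- reaction_state(c_precursor = 1e-8, c_ta = 2e-4)
  t_grid <- seq(0, 60, by = 0.5)
  tr <- simulate_reduction(st, p, t_grid)
  analytic <- pseudo_first_order_decay(1e-8, 2e-4, p, t_grid)
  expect_lt(max(abs(tr$c_precursor_M - analytic) / analytic), 1e-4)
})

test_that("adaptive integration agrees with a fixed-step reference integrator", {
  st <- seed_state()
  p <- rate_parameters()
  t_grid <- seq(0, 60, by = 5)
  adaptive <- simulate_reduction(st, p, t_grid)
  fixed <- simulate_reduction_fixed_step(st, p, t_grid, dt = 1e-3)
  rel <- abs(adaptive$c_precursor_M - fixed$c_precursor_M) /
    st$c_precursor
  expect_lt(max(rel), 1e-4)
  rel_ta <- abs(adaptive$c_ta_M - fixed$c_ta_M) / st$c_ta
  expect_lt(max(rel_ta), 1e-4)
})

test_that("TA depletion is much faster than precursor decay when TA limits", {
  # TA below the 3/20 stoichiometric requirement: the TA timescale is short
  st <- seed_state(c_ta = 1e-5)  # need (3/20) * 1.25e-4 = 1.875e-5
  tr <- simulate_reduction(st, rate_parameters(), seq(0, 5000, by = 10))
  t_ta <- tr$t_s[which(tr$c_ta_M < 0.01 * st$c_ta)[1]]
  t_au <- tr$t_s[which(tr$c_precursor_M < 0.01 * st$c_precursor)[1]]
  expect_false(is.na(t_ta))
  expect_true(is.na(t_au) || t_ta < t_au)
})

test_that("simulation validates its inputs", {
  st <- seed_state()
  expect_error(simulate_reduction(st, rate_parameters(), c(0, 0, 1)),
               "increasing")
  expect_error(simulate_reduction(st, rate_parameters(), c(5, 10)),
               "initial state")
  expect_error(rate_parameters(k_ta = -1), ">= 0")
  expect_error(rate_parameters(l = 0), "l must be > 0")
  expect_error(reaction_state(c_precursor = -1), ">= 0")
})

test_that("rate-constant fitting recovers generating parameters from noiseless traces", {
  p_true <- rate_parameters(k_ta = 600, l = 1.1)
  t_grid <- seq(0, 240, by = 8)
  traces <- lapply(c(5e-5, 1e-4, 2e-4), function(cta) {
    simulate_reduction(seed_state(c_ta = cta), p_true, t_grid)
  })
  guess <- rate_parameters(k_ta = 200, l = 1.4)
  fit <- fit_rate_constants(traces, guess, fixed = c("k_cit", "k_pass"))
  expect_lt(abs(fit$k_ta - 600) / 600, 0.01)
  expect_lt(abs(fit$l - 1.1) / 1.1, 0.01)
  expect_true(attr(fit, "converged"))
})

test_that("fitting a zero-dynamics trace with everything fixed returns the guess", {
  p0 <- rate_parameters(k_ta = 0, k_cit = 0, k_pass = 0)
  tr <- simulate_reduction(seed_state(), p0, seq(0, 50, by = 5))
  out <- fit_rate_constants(tr, p0,
                            fixed = c("k_ta", "l", "k_cit", "k_pass"))
  expect_identical(out$k_ta, 0)
  expect_identical(out$l, p0$l)
})
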