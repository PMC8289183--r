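test_that("particle number concentration follows the bulk-gold density relation", {
  # frozen from independent arithmetic with M_Au = 196.97 g/mol,
  # rho_Au = 19.3 g/cm^3: (1.25e-4 * 196.97 / 1000) / (19.3 * pi/6 * 27e-21)
  expect_equal(particle_number_concentration(1.25e-4, 3),
               90238195569403.08, tolerance = 1e-9)
  expect_identical(particle_number_concentration(0, 3), 0)
  # cube law: doubling the diameter at fixed gold gives N/8
  expect_equal(particle_number_concentration(1.25e-4, 6),
               particle_number_concentration(1.25e-4, 3) / 8,
               tolerance = 1e-12)
  expect_error(particle_number_concentration(1e-4, 0), "positive")
})

test_that("total surface area is N * pi * d^2", {
  n <- particle_number_concentration(1.25e-4, 3)
  expect_equal(total_surface_area(n, 3), pi * 9 * n, tolerance = 1e-12)
  expect_equal(total_surface_area(n, 3), 2551424870466322.0,
               tolerance = 1e-9)
  expect_identical(total_surface_area(0, 3), 0)
  expect_equal(total_surface_area(n, 6), 4 * total_surface_area(n, 3),
               tolerance = 1e-12)
})

test_that("gold-per-particle and diameter conversions invert each other", {
  d <- c(3, 5.5, 15)
  expect_equal(diameter_from_gold(gold_per_particle(d)), d,
               tolerance = 1e-12)
  cs <- colloid_state(25, 1.25e-4, 3)
  expect_equal(cs$n_conc * gold_per_particle(3) * 1000, cs$c_au,
               tolerance = 1e-9)
})

test_that("recipe simulation reproduces an independent bookkeeping oracle", {
  report <- simulate_recipe(default_recipe())
  oracle_d <- recipe_bookkeeping_oracle()
  expect_equal(report$d_theoretical_nm[-1], oracle_d, tolerance = 1e-6)
  # cumulative concentrations hit the published targets exactly
  expect_equal(report$c_au_M,
               c(1.25e-4, 1.5e-4, 1.75e-4, 2e-4, 2.25e-4, 2.5e-4, 2.75e-4,
                 3e-4))
})

test_that("gold and particle balances close across every simulated round", {
  recipe <- default_recipe()
  report <- simulate_recipe(recipe)
  v_extract <- 10
  # reconstruct total moles: flask + extracted must equal seed + dosed
  in_flask <- report$c_au_M * report$volume_ml / 1000
  extracted <- cumsum(c(0, report$c_au_M[-nrow(report)] * v_extract / 1000))
  dosed <- cumsum(report$v_stock_added_ml * recipe$c_stock / 1000)
  total <- in_flask + extracted
  expected <- report$c_au_M[1] * report$volume_ml[1] / 1000 + dosed
  expect_lt(max(abs(total - expected) / expected), 1e-9)
  # particle count conserved within each round up to the extraction factor
  n_total <- report$n_conc_per_ml * report$volume_ml
  keep <- (report$volume_ml[-nrow(report)] - v_extract) /
    report$volume_ml[-nrow(report)]
  expect_lt(max(abs(n_total[-1] / n_total[-length(n_total)] - keep)), 1e-9)
})

test_that("degenerate and growth-doubling rounds behave per the mass law", {
  # no extraction, no added gold: state unchanged
  seed <- colloid_state(25, 1.25e-4, 3)
  idle <- default_recipe(rounds = list(
    synthesis_round(1, 1.25e-4, v_extract_ml = 0, v_replace_ml = 0)))
  rep_idle <- simulate_recipe(idle, seed = seed)
  expect_equal(rep_idle$d_theoretical_nm[2], 3, tolerance = 1e-12)
  expect_equal(rep_idle$volume_ml[2], 25)
  expect_equal(rep_idle$n_conc_per_ml[2], seed$n_conc, tolerance = 1e-12)

  # a round multiplying gold per particle by 8 doubles the diameter
  planned <- plan_dosing(6, seed, synthesis_round(1, 0, v_extract_ml = 0,
                                                  v_replace_ml = 0))
  rep8 <- simulate_recipe(planned, seed = seed)
  expect_equal(rep8$d_theoretical_nm[2], 6, tolerance = 1e-9)

  # n identical doublings of gold per particle: d = d0 * 2^(n/3)
  targets <- 3 * 2^((1:4) / 3)
  planned_n <- plan_dosing(targets, seed,
                           synthesis_round(1, 0, v_extract_ml = 0,
                                           v_replace_ml = 0))
  rep_n <- simulate_recipe(planned_n, seed = seed)
  expect_equal(rep_n$d_theoretical_nm[-1], targets, tolerance = 1e-9)
})

test_that("infeasible rounds raise planning errors naming the round", {
  seed <- colloid_state(25, 2e-4, 3)
  low_target <- default_recipe(rounds = list(synthesis_round(1, 1e-5)))
  expect_error(simulate_recipe(low_target, seed = seed),
               "round 1.*below the post-extraction residual")
  big_extract <- default_recipe(rounds = list(
    synthesis_round(1, 3e-4, v_extract_ml = 30)))
  expect_error(simulate_recipe(big_extract, seed = seed),
               "round 1.*exceeds")
  expect_error(plan_dosing(c(5, 4), seed), "increasing")
  expect_error(plan_dosing(2, seed), "below the seed")
})

test_that("dosing design round-trips through the forward simulation", {
  # forward-simulate the published recipe, then recover its targets
  forward <- simulate_recipe(default_recipe())
  seed <- colloid_state(25, 1.25e-4, 3)
  planned <- plan_dosing(forward$d_theoretical_nm[-1], seed)
  recovered <- vapply(planned$rounds, function(r) r$c_au_final_target,
                      numeric(1))
  published <- c(1.5e-4, 1.75e-4, 2e-4, 2.25e-4, 2.5e-4, 2.75e-4, 3e-4)
  expect_equal(recovered, published, tolerance = 1e-9)
  # and the planned recipe reproduces the diameters to 1e-6 nm
  replay <- simulate_recipe(planned, seed = seed)
  expect_lt(max(abs(replay$d_theoretical_nm[-1] -
                      forward$d_theoretical_nm[-1])), 1e-6)
  # single target at the seed diameter needs no gold
  no_growth <- plan_dosing(3, seed, synthesis_round(1, 0, v_extract_ml = 0,
                                                    v_replace_ml = 0))
  expect_equal(no_growth$rounds[[1]]$c_au_final_target, seed$c_au,
               tolerance = 1e-12)
})

test_that("dilution factors equalize surface areas with the smallest-area reference", {
  # identical samples: all factors 1
  same <- dilution_factors(tibble::tibble(c_au_M = rep(1e-4, 3),
                                          d_core_nm = rep(5, 3)))
  expect_equal(same$df, rep(1, 3))
  # 2:1 surface ratio
  two <- dilution_factors(tibble::tibble(s_total_nm2_per_ml = c(2, 1)))
  expect_equal(two$df, c(2, 1))
  # published series: the largest particle is the reference
  tab <- published_round_targets()
  dfs <- dilution_factors(tibble::tibble(label = tab$label,
                                         c_au_M = tab$c_au_M,
                                         d_core_nm = tab$d_nominal_nm))
  expect_identical(dfs$label[dfs$df == 1], "uGNP_15")
  expect_true(all(dfs$df >= 1))
  expect_identical(sum(dfs$df == 1), 1L)
  # applying the factors equalizes the areas exactly
  expect_equal(dfs$s_total_nm2_per_ml / dfs$df,
               rep(min(dfs$s_total_nm2_per_ml), nrow(dfs)),
               tolerance = 1e-12)
  # scale invariance
  dfs2 <- dilution_factors(tibble::tibble(
    s_total_nm2_per_ml = dfs$s_total_nm2_per_ml * 7.3))
  expect_equal(dfs2$df, dfs$df, tolerance = 1e-12)
  expect_error(dilution_factors(tibble::tibble(s_total_nm2_per_ml = c(0, 0))),
               "zero")
})

test_that("ligand surface density is a guarded ratio", {
  expect_identical(ligand_surface_density(0, 50), 0)
  expect_equal(ligand_surface_density(100, 50), 2)
  s <- total_surface_area(particle_number_concentration(1.25e-4, 3), 3)
  expect_equal(ligand_surface_density(3.3 * s, s), 3.3, tolerance = 1e-12)
  expect_error(ligand_surface_density(10, 0), "> 0")
})
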