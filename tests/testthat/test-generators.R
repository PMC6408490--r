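test_that("noiseless reactant decay matches the closed form", {
  spec <- generator_spec(std_condition(), true_k = 62, noise_cv = 0,
                         sample_times = c(1, 2.236, 4))
  p <- simulate_profile(spec, 1)
  expect_equal(p$reactant, spec$r0 * exp(-62 * 0.005 * p$times),
               tolerance = 1e-12)
  # t = 2.236 ks is one half-life (ln2 / 0.31 ks^-1): R/R0 ~ 0.50
  expect_equal(p$reactant[2] / spec$r0, 0.5, tolerance = 1e-3)
})

test_that("zero rate constant leaves the reactant untouched", {
  spec <- generator_spec(std_condition(), true_k = 0, noise_cv = 0)
  p <- simulate_profile(spec, 1)
  expect_equal(p$reactant, rep(spec$r0, length(p$times)))
  expect_equal(p$primary, rep(0, length(p$times)))
  expect_equal(p$secondary, rep(0, length(p$times)))
})

test_that("mass is conserved across the branched consecutive network", {
  # selectivity = 1, no degradation: R + P = R0 exactly
  spec <- generator_spec(std_condition(), true_k = 62, selectivity = 1,
                         k_deg = 0, noise_cv = 0)
  p <- simulate_profile(spec, 1)
  expect_equal(p$reactant + p$primary, rep(spec$r0, length(p$times)),
               tolerance = 1e-12)

  # general case: R + P + S + humins = R0, humins >= 0
  set.seed(42)
  for (i in 1:10) {
    s <- runif(1)
    spec <- generator_spec(std_condition(), true_k = runif(1, 1, 100),
                           selectivity = s, k_deg = runif(1, 0, 50),
                           noise_cv = 0)
    p <- simulate_profile(spec, 1)
    humins <- (1 - s) * (spec$r0 - p$reactant)
    expect_true(all(humins >= -1e-12))
    expect_equal(p$reactant + p$primary + p$secondary + humins,
                 rep(spec$r0, length(p$times)), tolerance = 1e-9)
  }
})

test_that("profiles are reproducible from the seed", {
  spec <- generator_spec(std_condition(), 62, noise_cv = 0.05, seed = 11)
  p1 <- simulate_profile(spec, 1)
  p2 <- simulate_profile(spec, 1)
  expect_identical(p1$reactant, p2$reactant)
  spec2 <- generator_spec(std_condition(), 62, noise_cv = 0.05, seed = 12)
  p3 <- simulate_profile(spec2, 1)
  expect_false(identical(p1$reactant, p3$reactant))
})

test_that("generator validates its inputs", {
  expect_error(generator_spec(std_condition(), 62, selectivity = 1.2),
               "selectivity")
  expect_error(generator_spec(std_condition(), -1), "rate constants")
  expect_error(generator_spec(std_condition(), 62,
                              sample_times = c(2, 1)), "increasing")
  expect_error(generator_spec(std_condition(), 62,
                              sample_times = c(-1, 1)), "nonnegative")
  spec <- generator_spec(std_condition(), 62)
  expect_error(simulate_profile(spec, 5), "out of range")
  expect_error(simulate_profile(spec, experiment_condition(0.5)),
               "not present")
})

test_that("chloride tables follow the saturation-enhancement law", {
  des <- chloride_design(solvent_fractions = 0.9, k_o = 10, K_Cl = 2,
                         r_enhance = 5, cl_grid = c(0, 0.5, 100))
  tab <- generate_chloride_table(des, noise_cv = 0, seed = 1)
  expect_equal(tab$k_obs[1], 10)               # zero chloride: baseline
  expect_equal(tab$k_obs[2], 35)               # f = 0.5 -> 10 * 3.5
  expect_equal(tab$k_obs[3], 10 * 6, tolerance = 0.01)  # near saturation
  # monotone nondecreasing in chloride at zero noise
  des2 <- chloride_design()
  tab2 <- generate_chloride_table(des2, noise_cv = 0)
  for (s in unique(tab2$solvent)) {
    k <- tab2$k_obs[tab2$solvent == s]
    expect_true(all(diff(k) >= 0))
  }
  expect_error(chloride_design(cl_grid = c(-0.1, 1)), ">= 0")
  # determinism
  t1 <- generate_chloride_table(des2, noise_cv = 0.05, seed = 4)
  t2 <- generate_chloride_table(des2, noise_cv = 0.05, seed = 4)
  expect_identical(t1, t2)
})

test_that("Arrhenius sets follow k = exp(lnA - Ea/RT)", {
  flat <- generate_arrhenius_set(Ea = 0, lnA = 2,
                                 temperatures = c(350, 375, 400))
  expect_equal(flat$k, rep(exp(2), 3))
  # closed-form temperature ratio at Ea = 110 kJ/mol
  s <- generate_arrhenius_set(110, 30, c(373, 393))
  expect_equal(s$k[2] / s$k[1],
               exp(110 / R_GAS * (1 / 373 - 1 / 393)), tolerance = 1e-12)
  expect_error(generate_arrhenius_set(110, 30, numeric(0)), "empty")
  expect_error(generate_arrhenius_set(110, 30, c(-10, 300)), "> 0")
  a1 <- generate_arrhenius_set(110, 30, c(373, 393), 0.05, seed = 2)
  a2 <- generate_arrhenius_set(110, 30, c(373, 393), 0.05, seed = 2)
  expect_identical(a1, a2)
})
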