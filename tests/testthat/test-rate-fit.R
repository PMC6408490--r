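test_that("noiseless profiles are inverted exactly", {
  # GVL-like fast decay and water-like slow decay
  for (case in list(c(k = 62, h = 0.005), c(k = 0.14, h = 0.5))) {
    p <- make_profile(case["k"], acid_conc = case["h"])
    f <- fit_rate_constant(p)
    expect_lt(abs(f$k - case[["k"]]) / case[["k"]], 1e-6)
    expect_lt(diff(f$ci95), 1e-6 * case[["k"]])
    expect_true(f$converged)
    expect_equal(f$r0, 0.05, tolerance = 1e-6)
  }
})

test_that("estimator bias shrinks and RMSE scales with the noise level", {
  est <- function(cv) {
    ks <- vapply(1:60, function(i)
      fit_rate_constant(make_profile(62, noise_cv = cv, seed = i))$k, 0)
    c(bias = mean(ks) - 62, rmse = sqrt(mean((ks - 62)^2)))
  }
  lo <- est(0.02); hi <- est(0.08)
  expect_lt(abs(lo["bias"]) / 62, 0.01)
  expect_lt(lo["rmse"], hi["rmse"])
  # RMSE roughly proportional to noise CV (factor 4 here, allow 2-8)
  expect_gt(hi["rmse"] / lo["rmse"], 2)
  expect_lt(hi["rmse"] / lo["rmse"], 8)
})

test_that("wald and profile intervals agree on well-behaved data", {
  p <- make_profile(62, noise_cv = 0.05, seed = 3)
  fw <- fit_rate_constant(p, ci = "wald")
  fp <- fit_rate_constant(p, ci = "profile")
  expect_equal(fw$k, fp$k)
  expect_equal(fw$ci95, fp$ci95, tolerance = 0.05)
})

test_that("degenerate profiles are flagged, not reported as rates", {
  cond <- std_condition()
  flat <- kinetic_profile(cond, times = 1:5, reactant = rep(0.05, 5))
  f <- fit_rate_constant(flat)
  expect_false(f$converged)
  rising <- kinetic_profile(cond, 1:5, seq(0.01, 0.05, length.out = 5))
  expect_false(fit_rate_constant(rising)$converged)
  expect_error(fit_rate_constant(
    kinetic_profile(cond, 1, 0.05)), "at least 2")
})

test_that("salt-only experiments are referenced to the salt concentration", {
  cond <- experiment_condition(0.9, acid_conc = 0, salt_name = "KCl",
                               salt_conc = 0.005, anion = "Cl-")
  spec <- generator_spec(cond, true_k = 3.2, noise_cv = 0,
                         sample_times = seq(5, 100, by = 5))
  f <- fit_rate_constant(simulate_profile(spec, 1))
  expect_equal(f$mode, "salt_only")
  expect_equal(f$k, 3.2, tolerance = 1e-6)
  bare <- experiment_condition(0.9, acid_conc = 0)
  expect_error(
    fit_rate_constant(kinetic_profile(bare, 1:3, c(3, 2, 1) / 100)),
    "salt-only")
})

test_that("yield at target conversion follows the selectivity branch", {
  # no degradation: yield = selectivity * conversion exactly
  p <- make_profile(62, selectivity = 0.78, k_deg = 0, n_times = 200)
  y <- compute_yield(p, 0.9)
  expect_equal(y$yield, 0.702, tolerance = 1e-3)
  expect_equal(y$selectivity, 0.78, tolerance = 1e-3)
  expect_lte(y$yield, y$conversion)

  expect_equal(compute_yield(p, 0)$yield, 0)
  noP <- kinetic_profile(std_condition(), p$times, p$reactant)
  y0 <- compute_yield(noP, 0.9)
  expect_equal(y0$yield, 0)
  expect_equal(y0$selectivity, 0)

  # degradation lowers yield below the selectivity bound
  pd <- make_profile(62, selectivity = 0.78, k_deg = 30, n_times = 200)
  expect_lt(compute_yield(pd, 0.9)$yield, 0.702)

  # invariant to uniform concentration rescaling
  p2 <- kinetic_profile(p$condition, p$times, 3 * p$reactant,
                        3 * p$primary, 3 * p$secondary)
  expect_equal(compute_yield(p2, 0.9)$yield, y$yield, tolerance = 1e-12)

  short <- make_profile(62, n_times = 5)
  short <- kinetic_profile(short$condition, short$times[1:2],
                           short$reactant[1:2], short$primary[1:2])
  expect_error(compute_yield(short, 0.99), "max attained")
})

test_that("fold changes round half up for n-fold statements", {
  expect_equal(fold_change(62, 20), 3.1)
  expect_equal(fold_change(62, 20, "nearest_int"), 3)
  expect_equal(fold_change(95, 10), 9.5)
  expect_equal(fold_change(95, 10, "nearest_int"), 10)
  expect_equal(fold_change(5, 5), 1)
  expect_error(fold_change(5, 0), "zero")
  # reciprocal property
  set.seed(1)
  for (i in 1:10) {
    a <- runif(1, 0.1, 100); b <- runif(1, 0.1, 100)
    expect_equal(fold_change(a, b) * fold_change(b, a), 1,
                 tolerance = 1e-12)
  }
})

test_that("KIE ratios recover the generator value and classify inversion", {
  fD <- fit_rate_constant(make_profile(62 * 1.7, isotope = "D"))
  fH <- fit_rate_constant(make_profile(62))
  r <- kie_ratio(fD, fH)
  expect_equal(r$ratio, 1.7, tolerance = 1e-5)
  expect_true(r$inverse)
  same <- kie_ratio(fH, fH)
  expect_equal(same$ratio, 1)
  expect_false(same$inverse)
})
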