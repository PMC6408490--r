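test_that("saturation fraction is bounded and monotone", {
  expect_equal(saturation_fraction(2, 0), 0)
  expect_equal(saturation_fraction(1, 1), 0.5)
  expect_equal(saturation_fraction(4, 1), 0.8)
  expect_error(saturation_fraction(-1, 1), ">= 0")
  expect_error(saturation_fraction(1, -1), ">= 0")
  set.seed(9)
  for (i in 1:20) {
    K <- runif(1, 0, 50)
    cl <- sort(runif(6, 0, 3))
    f <- saturation_fraction(K, cl)
    expect_true(all(f >= 0 & f <= 1))
    expect_true(all(diff(f) >= 0))
    # monotone in K at fixed cl too
    expect_true(all(diff(saturation_fraction(sort(runif(5, 0, 50)),
                                             cl[3])) >= 0))
  }
})

test_that("enhanced rate has the right limits and is concave in chloride", {
  expect_equal(enhanced_rate(10, 5, 2, 0), 10)
  expect_equal(enhanced_rate(10, 5, 2, 0.5), 35)
  expect_equal(enhanced_rate(10, 5, 2, 1e9), 60, tolerance = 1e-6)
  expect_error(enhanced_rate(-1, 5, 2, 1), ">= 0")
  set.seed(5)
  for (i in 1:20) {
    cl <- sort(runif(8, 0, 3))
    k <- enhanced_rate(runif(1, 0.1, 50), runif(1, 0, 10),
                       runif(1, 0.1, 30), cl)
    expect_true(all(diff(k) >= 0))
    # chord slopes decrease along any increasing grid (concave down)
    slopes <- diff(k) / diff(cl)
    expect_true(all(diff(slopes) <= 1e-9))
  }
})

test_that("single-solvent fits invert noiseless tables exactly", {
  des <- chloride_design(solvent_fractions = 0.9, k_o = 10, K_Cl = 2,
                         r_enhance = 5)
  tab <- generate_chloride_table(des, noise_cv = 0)
  fit <- fit_chloride(tab)
  expect_equal(unname(coef(fit)["r_enhance"]), 5, tolerance = 1e-6)
  expect_equal(fit$per_solvent$r_o, 10, tolerance = 1e-6)
  expect_equal(fit$per_solvent$K_Cl, 2, tolerance = 1e-6)
  expect_true(fit$identifiable)
})

test_that("flat tables flag K_Cl as unidentifiable instead of erroring", {
  tab <- data.frame(cl_M = c(0, 0.1, 0.5, 1, 2), k_obs = rep(10, 5))
  fit <- fit_chloride(tab)
  expect_lt(fit$r_enhance, 0.01)
  expect_false(fit$identifiable)
  expect_equal(unname(fit$per_solvent$K_Cl_high), Inf)
})

test_that("noisy single-solvent fits recover K_Cl within 15% in median", {
  des <- chloride_design(solvent_fractions = 0.9, k_o = 10, K_Cl = 2,
                         r_enhance = 5)
  err <- vapply(1:200, function(i) {
    tab <- generate_chloride_table(des, noise_cv = 0.05, seed = i)
    abs(fit_chloride(tab)$per_solvent$K_Cl - 2) / 2
  }, 0)
  expect_lt(stats::median(err), 0.15)
})

test_that("global fit shares the enhancement factor across solvents", {
  des <- chloride_design()
  tab <- generate_chloride_table(des, noise_cv = 0)
  fit <- fit_chloride(tab, shared = TRUE)
  expect_equal(fit$r_enhance, 5, tolerance = 1e-6)
  expect_equal(fit$per_solvent$r_o, des$k_o, tolerance = 1e-5)
  expect_equal(fit$per_solvent$K_Cl, des$K_Cl, tolerance = 1e-5)
  expect_true(all(fit$per_solvent$r_squared > 0.999))
})

test_that("shared restriction costs fit quality when enhancements differ", {
  # generate each solvent with its own enhancement; the pooled shared fit
  # must have strictly larger SSE than the free per-solvent fits
  parts <- lapply(1:3, function(i) {
    d <- chloride_design(solvent_fractions = c(0.25, 0.5, 0.9)[i],
                         k_o = c(1, 5, 20)[i], K_Cl = c(2, 5, 20)[i],
                         r_enhance = c(2, 5, 9)[i])
    generate_chloride_table(d, noise_cv = 0.02, seed = i)
  })
  tab <- do.call(rbind, parts)
  fit <- fit_chloride(tab, shared = TRUE)
  expect_gt(fit$f_test$sse_shared, fit$f_test$sse_free)
  # and the F test detects the violated restriction
  expect_lt(fit$f_test$p_value, 0.01)
  free <- fit_chloride(tab, shared = FALSE)
  expect_equal(unname(free$r_enhance), c(2, 5, 9), tolerance = 0.15)
})

test_that("global fit with one solvent reduces to the single-solvent fit", {
  des <- chloride_design(solvent_fractions = 0.5, k_o = 3, K_Cl = 5,
                         r_enhance = 4)
  tab <- generate_chloride_table(des, noise_cv = 0.05, seed = 8)
  fit <- fit_chloride(tab, shared = TRUE)
  expect_equal(nrow(fit$per_solvent), 1)
  expect_true(fit$shared)
  expect_equal(fit$r_enhance, 4, tolerance = 0.2)
})

test_that("enhancement estimate is invariant to rescaling the rates", {
  des <- chloride_design()
  tab <- generate_chloride_table(des, noise_cv = 0.05, seed = 2)
  f1 <- fit_chloride(tab)
  tab2 <- tab; tab2$k_obs <- 100 * tab2$k_obs
  f2 <- fit_chloride(tab2)
  expect_equal(f1$r_enhance, f2$r_enhance, tolerance = 1e-6)
  expect_equal(f2$per_solvent$r_o, 100 * f1$per_solvent$r_o,
               tolerance = 1e-6)
})

test_that("fit_chloride validates its inputs", {
  expect_error(fit_chloride(data.frame(cl_M = c(0, 1, 2), k_obs = 1:3)),
               ">= 4")
  expect_error(fit_chloride(data.frame(cl_M = c(-1, 0, 1, 2),
                                       k_obs = 1:4)), ">= 0")
})

test_that("rate-constant vs K_Cl relation recovers an exact line", {
  K <- c(1.2, 2.5, 5, 12, 25)
  dat <- data.frame(K_Cl = K, k = 0.84 * K - 0.87)
  rel <- k_vs_kcl_relation(dat)
  expect_equal(rel$slope, 0.84, tolerance = 1e-9)
  expect_equal(rel$intercept, -0.87, tolerance = 1e-9)
  expect_equal(rel$r_squared, 1, tolerance = 1e-9)

  const <- data.frame(K_Cl = K, k = rep(2, 5))
  rel0 <- k_vs_kcl_relation(const)
  expect_equal(rel0$slope, 0)
  expect_equal(rel0$r_squared, 0)

  expect_error(k_vs_kcl_relation(dat[1:2, ]), "at least 3")
})

test_that("OLS slope CI covers the true slope at the nominal rate", {
  hits <- vapply(1:200, function(i) {
    set.seed(1000 + i)
    K <- c(1.2, 2.5, 5, 12, 25)
    y <- 0.84 * K - 0.87 + rnorm(5, sd = 0.5)
    rel <- k_vs_kcl_relation(data.frame(K_Cl = K, k = y))
    ci <- stats::confint(rel$lm)["K_Cl", ]
    ci[1] <= 0.84 && 0.84 <= ci[2]
  }, TRUE)
  expect_gte(mean(hits), 0.90)
})
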