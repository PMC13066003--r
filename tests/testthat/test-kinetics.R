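test_that("initial_rate recovers slopes from progress curves", {
  t <- seq(0, 100, by = 1)
  expect_equal(initial_rate(t, 3 + 2.0 * t), 2.0)

  # A(1 - exp(-k t)): the true initial rate is A*k
  tt <- seq(0, 400, by = 0.5)
  y <- 100 * (1 - exp(-0.01 * tt))
  expect_equal(initial_rate(tt, y), 1.0, tolerance = 0.05)

  expect_error(initial_rate(c(0, 1, 2), c(1, 2, 3)), "at least 4")
  expect_error(initial_rate(c(0, 2, 1, 3), c(1, 2, 3, 4)), "increasing")
})

test_that("Michaelis-Menten fit: self-consistency and the Km midpoint", {
  x <- c(5, 10, 25, 50, 100, 250, 500, 1000, 2000)
  y <- 10 * x / (50 + x)
  fit <- fit_michaelis_menten(x, y, enzyme_conc = 0.15)
  expect_true(fit$converged)
  expect_equal(fit$vmax, 10, tolerance = 1e-6)
  expect_equal(fit$km, 50, tolerance = 1e-6)
  # kcat = Vmax / [E] exactly; efficiency = kcat / Km
  expect_identical(fit$kcat, fit$vmax / 0.15)
  expect_identical(fit$efficiency, fit$kcat / fit$km)
  # predicted rate at X = Km is Vmax / 2
  expect_equal(fit$vmax * fit$km / (fit$km + fit$km), fit$vmax / 2)

  expect_error(fit_michaelis_menten(c(1, 2, 3, 4), c(1, 2, 3, 4), 1),
               "5 distinct")
})

test_that("MM fit residual gradient vanishes at the optimum", {
  g <- gen_kinetics(8, 120, 0.2, c(10, 30, 100, 300, 1000, 3000),
                    noise_frac = 0.04, seed = 31)
  fit <- fit_michaelis_menten(g$data$substrate, g$data$rate, 0.2)
  expect_true(fit$converged)
  # first-order optimality of the least-squares objective
  x <- g$data$substrate; y <- g$data$rate
  resid <- y - fit$vmax * x / (fit$km + x)
  d_vmax <- sum(resid * x / (fit$km + x))
  d_km <- sum(resid * (-fit$vmax * x / (fit$km + x)^2))
  scale <- sum(abs(resid)) + 1
  expect_lt(abs(d_vmax) / scale, 1e-4)
  expect_lt(abs(d_km) / scale, 1e-4)
})

test_that("Km recovery under 5% noise (reduced-seed smoke check)", {
  # 30-seed smoke version of the 200-seed acceptance simulation
  errs <- vapply(1:30, function(k) {
    g <- gen_kinetics(10, 50, 0.15, c(5, 10, 25, 50, 100, 250, 500, 1000,
                                      2000),
                      noise_frac = 0.05, seed = 100 + k)
    fit <- fit_michaelis_menten(g$data$substrate, g$data$rate, 0.15)
    abs(fit$km - 50) / 50
  }, numeric(1))
  expect_lte(median(errs), 0.10)
})

test_that("efficiency_ratio identity, scaling and antisymmetry", {
  x <- c(5, 10, 25, 50, 100, 250, 500, 1000, 2000)
  fit1 <- fit_michaelis_menten(x, 10 * x / (50 + x), 0.15)
  fit2 <- fit_michaelis_menten(x, 20 * x / (50 + x), 0.15)
  expect_equal(efficiency_ratio(fit1, fit1), 1.0)
  expect_equal(efficiency_ratio(fit2, fit1), 2.0, tolerance = 1e-6)
  # antisymmetry r(A,B) * r(B,A) = 1
  expect_equal(efficiency_ratio(fit1, fit2) * efficiency_ratio(fit2, fit1),
               1.0, tolerance = 1e-12)

  bad <- fit1; bad$converged <- FALSE
  expect_error(efficiency_ratio(bad, fit1), "converged")
})

test_that("a 1.6-fold efficiency difference is recovered under 3% noise", {
  x <- c(5, 10, 25, 50, 100, 250, 500, 1000, 2000)
  ok <- vapply(1:200, function(k) {
    gv <- gen_kinetics(16, 50, 0.15, x, noise_frac = 0.03, seed = 700 + k)
    gr <- gen_kinetics(10, 50, 0.15, x, noise_frac = 0.03, seed = 7000 + k)
    fv <- fit_michaelis_menten(gv$data$substrate, gv$data$rate, 0.15)
    fr <- fit_michaelis_menten(gr$data$substrate, gr$data$rate, 0.15)
    r <- efficiency_ratio(fv, fr)
    r >= 1.4 && r <= 1.8
  }, logical(1))
  expect_gte(mean(ok), 0.90)
})

test_that("activation_profile folds, flags and errors", {
  # flat profile: all folds 1, flagged
  pr <- activation_profile(c(0, 0.1, 1, 10), c(100, 100, 100, 100))
  expect_equal(pr$fold_activation, rep(1, 3))
  expect_true(pr$flat)

  # baseline 100, top 400 -> max fold 4, not flat
  pr2 <- activation_profile(c(0, 0.1, 1, 10), c(100, 150, 300, 400))
  expect_equal(pr2$max_fold, 4.0)
  expect_false(pr2$flat)

  # synthetic saturating activation with fold 3 recovered within 10%
  conc <- c(0, 0.01, 0.03, 0.1, 0.3, 1, 3, 10)
  act <- 100 * (1 + 2 * conc / (0.2 + conc))
  set.seed(77)
  act_noisy <- act * (1 + rnorm(length(act), 0, 0.03))
  act_noisy[1] <- act[1]
  pr3 <- activation_profile(conc, act_noisy)
  expect_equal(pr3$max_fold, 3, tolerance = 0.1)

  expect_error(activation_profile(c(0.1, 1), c(1, 2)), "baseline")
  expect_error(activation_profile(c(0, 1), c(-5, 2)), "> 0")
})

test_that("4PL IC50 fit: self-consistency and plateau midpoint", {
  d <- 10^seq(-3, 2, length.out = 10)
  y <- 20 + (120 - 20) / (1 + (d / 0.5)^1)
  fit <- fit_ic50(d, y)
  expect_true(fit$converged)
  expect_equal(fit$ic50, 0.5, tolerance = 1e-6)
  expect_equal(fit$hill, 1, tolerance = 1e-5)
  # response at the fitted IC50 equals (top + bottom) / 2
  at_ic50 <- fit$bottom + (fit$top - fit$bottom) /
    (1 + (fit$ic50 / fit$ic50)^fit$hill)
  expect_equal(at_ic50, (fit$top + fit$bottom) / 2)

  # no transition -> converged = FALSE
  flat <- fit_ic50(d, rep(50, 10))
  expect_false(flat$converged)
  # increasing trend -> converged = FALSE
  inc <- fit_ic50(d, seq(10, 100, length.out = 10))
  expect_false(inc$converged)
  expect_error(fit_ic50(c(1, 2, 3, 4, 5), c(5, 4, 3, 2, 1)), "6 distinct")
})

test_that("IC50 recovery under 5% noise (reduced-seed smoke check)", {
  # 30-seed smoke version of the 200-seed acceptance simulation
  errs <- vapply(1:30, function(k) {
    g <- gen_inhibition(0.5, 1, 120, 20, 10^seq(-3, 2, length.out = 10),
                        noise_frac = 0.05, seed = 300 + k)
    fit <- fit_ic50(g$data$dose, g$data$response)
    abs(log10(fit$ic50 / 0.5))
  }, numeric(1))
  expect_lte(median(errs), 0.1)
})

test_that("melt_tm finds the sigmoid inflection and rejects linear traces", {
  g <- gen_melt(55, seed = 1)                      # noiseless
  mr <- melt_tm(g$data$temperature, g$data$fluorescence)
  expect_equal(mr$tm, 55.0, tolerance = 0.2)

  grid <- seq(25, 99, by = 0.1)
  expect_error(melt_tm(grid, 10 + 3 * grid), "no transition")

  # affine invariance: scale and offset leave Tm unchanged
  mr2 <- melt_tm(g$data$temperature, 7.5 * g$data$fluorescence - 1234)
  expect_equal(mr2$tm, mr$tm, tolerance = 1e-10)
})

test_that("Tm recovery at 2% amplitude noise (reduced-seed smoke check)", {
  # 20-seed smoke version of the 100-seed acceptance simulation
  ok <- vapply(1:20, function(k) {
    g <- gen_melt(55, noise_frac = 0.02, seed = 400 + k)
    abs(melt_tm(g$data$temperature, g$data$fluorescence)$tm - 55) <= 0.5
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("fits are deterministic for identical inputs", {
  g <- gen_kinetics(10, 50, 0.15, c(5, 20, 80, 300, 1200), noise_frac = 0.05,
                    seed = 9)
  f1 <- fit_michaelis_menten(g$data$substrate, g$data$rate, 0.15)
  f2 <- fit_michaelis_menten(g$data$substrate, g$data$rate, 0.15)
  expect_identical(f1$vmax, f2$vmax)
  expect_identical(f1$km, f2$km)
})
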