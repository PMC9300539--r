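# Population simulation layer: random-effect draws, residual error,
# exposure metrics.

test_that("individual draws honour the variance specification", {
  spec <- pax_cfg$random_effects
  # zero variability: the typical subject, exactly
  ind0 <- sample_individual(zero_re_config()$random_effects, 3,
                            seed = 1)
  expect_true(all(ind0$eta == 0) && all(ind0$bov == 0))
  # reproducibility
  a <- sample_individual(spec, 2, seed = 99)
  b <- sample_individual(spec, 2, seed = 99)
  expect_identical(a, b)
  # empirical CV of exp(eta) matches the lognormal moment formula
  set.seed(4)
  omega <- cv_to_omega(25.1)
  draws <- exp(rnorm(1e5) * omega)
  expect_equal(sd(draws) / mean(draws), sqrt(exp(omega^2) - 1),
               tolerance = 0.02)
  # draws through sample_individual carry the same omega
  set.seed(5)
  etas <- replicate(2e4, sample_individual(spec, 0)$eta[["clint0"]])
  expect_equal(sd(etas), omega, tolerance = 0.02)
})

test_that("proportional residual error has the stated spread and
           preserves zero predictions", {
  expect_identical(apply_residual_error(c(1, 2, 0), 0), c(1, 2, 0))
  set.seed(6)
  obs <- apply_residual_error(rep(100, 1e5), 0.258)
  expect_equal(sd(obs / 100 - 1), 0.258, tolerance = 0.02)
  expect_identical(apply_residual_error(0, 0.5, seed = 1), 0)
})

test_that("exposure metrics match closed forms", {
  prof <- data.frame(time = seq(0, 24, by = 0.1),
                     conc_pac = rep(100, 241))
  m <- pk_metrics(prof, threshold = 42.7)
  expect_equal(m$auc, 2400)
  expect_equal(m$time_above, 24)
  expect_equal(m$cmax, 100)

  low <- transform(prof, conc_pac = conc_pac * 0.1)
  expect_equal(pk_metrics(low, threshold = 42.7)$time_above, 0)

  # quadratic refinement recovers an off-grid peak of a parabola
  tt <- seq(0, 10, by = 0.5)
  par <- data.frame(time = tt, conc_pac = 50 - (tt - 3.26)^2)
  mp <- pk_metrics(par, threshold = 1e9)
  expect_equal(mp$tmax, 3.26, tolerance = 1e-6)
  expect_equal(mp$cmax, 50, tolerance = 1e-6)

  # one-compartment bolus: AUC over a long window equals dose / CL
  cl <- 5; v <- 50; dose <- 1e5
  tt <- seq(0, 400, by = 0.05)
  bol <- data.frame(time = tt, conc_pac = dose / v * exp(-cl / v * tt))
  expect_equal(pk_metrics(bol)$auc, dose / cl, tolerance = 1e-3)

  expect_error(pk_metrics(prof, window = c(0, 48)), "window outside")
})

test_that("threshold crossings are interpolated linearly", {
  prof <- data.frame(time = 0:4, conc_pac = c(0, 100, 100, 0, 0))
  # up-crossing at t where 100 t = 42.7; down at 2 + (100-42.7)/100
  m <- pk_metrics(prof, threshold = 42.7)
  expect_equal(m$time_above, (2 + 0.573) - 0.427, tolerance = 1e-12)
})

test_that("population simulation is seeded and heterogeneous", {
  reg <- single_dose_regimen(30, "capsule", by = 1)
  pop1 <- simulate_population(reg, pax_cfg, n = 3, seed = 11)
  pop2 <- simulate_population(reg, pax_cfg, n = 3, seed = 11)
  expect_identical(pop1, pop2)
  aucs <- tapply(pop1$auc_pac, pop1$id, max)
  expect_gt(diff(range(aucs)), 0)
})

test_that("between-subject spread of simulated exposure grows with the
           bioavailability variance", {
  reg <- single_dose_regimen(30, "capsule", by = 4)
  reg$grid <- 0.5 + c(4, 24)
  cv_of_auc <- function(rf_cv) {
    cfg <- pax_cfg
    cfg$random_effects <- random_effects_spec(
      bsv_cv = c(alpha = 0, clint0 = 0, vc = 0, rf_gut = rf_cv),
      bov_cv = c(rf_gut = 0), sigma_prop_pk = 0)
    pop <- simulate_population(reg, cfg, n = 60, seed = 21)
    aucs <- tapply(pop$auc_pac, pop$id, max)
    sd(aucs) / mean(aucs)
  }
  cvs <- vapply(c(0, 20, 60), cv_of_auc, numeric(1))
  expect_true(all(diff(cvs) > 0))
  expect_lt(cvs[1], 1e-10)
})
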