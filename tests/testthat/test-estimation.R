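# Mixed-effects machinery: penalized individual objective, Laplace
# marginal likelihood, likelihood-ratio thresholds. The oracle checks
# use toy models with closed forms; model-based recovery lives in the
# acceptance suite.

test_that("penalized individual objective reduces to its closed form
           at a perfect fit and its minimizer matches a grid search", {
  y <- c(2, 5, 9)
  omega <- matrix(0.09, 1, 1)
  sigma <- 0.2
  # perfect fit at eta = 0: residual term is sum log(2 pi sigma^2 y^2)
  pf <- function(e) y * exp(e)
  g0 <- individual_penalized_nll(0, pf, y, omega, sigma)
  expect_equal(g0, sum(log(2 * pi * sigma^2 * y^2)) +
                 log(2 * pi * 0.09), tolerance = 1e-12)
  # huge omega: the penalty reduces to its normalizing constant
  big <- matrix(1e8, 1, 1)
  expect_equal(individual_penalized_nll(0, pf, y, big, sigma),
               sum(log(2 * pi * sigma^2 * y^2)) + log(2 * pi * 1e8),
               tolerance = 1e-9)
  # quadratic toy: brute-force grid oracle locates the same minimum
  yq <- c(2.2, 4.6, 9.9)
  gq <- function(e) individual_penalized_nll(e, pf, yq, omega, sigma)
  grid <- seq(-0.2, 0.2, by = 1e-6)
  e_grid <- grid[which.min(vapply(grid, gq, numeric(1)))]
  e_opt <- optimize(gq, c(-1, 1), tol = 1e-12)$minimum
  expect_lt(abs(e_opt - e_grid), 1e-6)
})

test_that("Laplace OFV is exact for linear-Gaussian subjects and
           additive over independent subjects", {
  set.seed(8)
  mu <- 10; omega <- 0.7; sigma <- 1.3
  subjects <- lapply(1:6, function(i) {
    yi <- mu + rnorm(1, 0, omega) + rnorm(4, 0, sigma)
    list(predict_fn = function(e) rep(mu + e, 4), y = yi)
  })
  fit <- laplace_marginal_nll(subjects, matrix(omega^2, 1, 1), sigma,
                              error = "additive")
  # closed-form marginal: y_i ~ N(mu 1, sigma^2 I + omega^2 J)
  V <- sigma^2 * diag(4) + omega^2
  Vi <- solve(V)
  exact <- sum(vapply(subjects, function(s) {
    r <- s$y - mu
    drop(determinant(2 * pi * V)$modulus[1] + t(r) %*% Vi %*% r)
  }, numeric(1)))
  expect_equal(fit$ofv, exact, tolerance = 1e-6)
  # empirical Bayes estimate equals the conjugate posterior mode
  eb <- omega^2 * sum(subjects[[1]]$y - mu) / (4 * omega^2 + sigma^2)
  expect_equal(fit$etas[[1]], eb, tolerance = 1e-5)
  # duplicating every subject doubles the OFV
  fit2 <- laplace_marginal_nll(c(subjects, subjects),
                               matrix(omega^2, 1, 1), sigma,
                               error = "additive")
  expect_equal(fit2$ofv, 2 * fit$ofv, tolerance = 1e-8)
})

test_that("with all variance components at zero the population fit
           matches a direct pooled-objective oracle", {
  cfg <- zero_re_config(sigma_pk = 20)
  trial <- generate_trial(mixed_single_dose_spec(4), cfg, seed = 12)
  cfg_init <- cfg
  cfg_init$paclitaxel$clint0 <- 400
  prob <- estimation_problem(trial, cfg_init, estimate_fixed = "clint0")
  fit <- fit_population(prob)

  # oracle: optimize the pooled objective directly over clint0
  pieces <- paxpkpd:::subject_pieces(trial)
  pooled <- function(log_cl) {
    cfg_x <- cfg_init
    cfg_x$paclitaxel$clint0 <- exp(log_cl)
    sum(vapply(pieces, function(p) {
      yh <- paxpkpd:::subject_predict(p, cfg_x, NULL, FALSE)$pac
      sum(log(2 * pi * 0.2^2 * yh^2) + (p$y_pac - yh)^2 / (0.2^2 * yh^2))
    }, numeric(1)))
  }
  oracle <- optimize(pooled, log(c(200, 2000)), tol = 1e-9)
  expect_equal(unname(fit$estimates["clint0"]), exp(oracle$minimum),
               tolerance = 1e-3)
  expect_equal(fit$ofv, oracle$objective, tolerance = 1e-4)
})

test_that("likelihood-ratio thresholds match the 1% chi-squared
           quantiles", {
  expect_true(lrt_compare(100, 106.64, df = 1)$significant)
  expect_false(lrt_compare(100, 106.62, df = 1)$significant)
  expect_true(lrt_compare(100, 109.22, df = 2)$significant)
  expect_false(lrt_compare(100, 109.20, df = 2)$significant)
  expect_equal(lrt_compare(1, 2, df = 3)$threshold, qchisq(0.99, 3))
  expect_warning(lrt_compare(10, 9, df = 1), "negative dOFV")
})

test_that("sequential PD stage returns the PK result untouched when no
           PD records exist", {
  cfg <- zero_re_config(sigma_pk = 20)
  trial <- generate_trial(mixed_single_dose_spec(2), cfg, seed = 12)
  prob <- estimation_problem(trial, cfg, estimate_fixed = character(0))
  pk <- fit_population(prob)
  expect_warning(out <- fit_pd_sequential(pk, trial), "no PD")
  expect_identical(out, pk)
})

test_that("the fast turnover propagator matches the full ODE solution", {
  cfg <- pax_cfg
  reg <- build_regimen(rp2d_design(n_days = 7,
                                   grid = seq(0, 168, by = 0.25)))
  prof <- simulate_typical(reg, cfg)
  s <- kin_stimulation(pmax(prof$conc_pac, 0), cfg$tsp1$ec50)
  G <- paxpkpd:::tsp_gain(prof$time, s, cfg$tsp1$kout)
  expect_equal(cfg$tsp1$baseline * G, prof$tsp1, tolerance = 1e-4)
})
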