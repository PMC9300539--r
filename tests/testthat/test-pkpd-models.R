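# Model equations: Weibull absorption, ritonavir-inhibited intrinsic
# clearance, well-stirred liver extraction, inverse-Gaussian input and
# the TSP-1 turnover model.

test_that("Weibull absorption rate matches the closed form", {
  # at t = alpha the rate is (beta/alpha) * exp(-1)
  expect_equal(weibull_absorption_rate(1.68, 1.68, 3.57),
               (3.57 / 1.68) * exp(-1), tolerance = 1e-12)
  expect_equal(weibull_absorption_rate(1.68, 1.68, 3.57), 0.7817,
               tolerance = 1e-4)
  # shape > 1: zero rate at the moment of dosing
  expect_identical(weibull_absorption_rate(0, 1.68, 3.57), 0)
  # shape 1 reduces to a first-order (exponential) rate
  t <- c(0.3, 1, 5)
  expect_equal(weibull_absorption_rate(t, 2, 1), exp(-t / 2) / 2,
               tolerance = 1e-12)
  expect_error(weibull_absorption_rate(1, -1, 2), "positive")
  expect_error(weibull_absorption_rate(-1, 1, 2), "non-negative")
})

test_that("intrinsic clearance follows the Imax inhibition model", {
  expect_equal(intrinsic_clearance(0, 746, 570, 375), 746)
  # half-maximal inhibition at the KI by construction
  expect_equal(intrinsic_clearance(375, 746, 570, 375), 746 - 570 / 2)
  # asymptote clint0 - imax
  expect_equal(intrinsic_clearance(1e12, 746, 570, 375), 176,
               tolerance = 1e-6)
  # monotone non-increasing in the ritonavir concentration
  cl <- intrinsic_clearance(seq(0, 5000, by = 50), 746, 570, 375)
  expect_true(all(diff(cl) <= 0))
  # an individual with low clint0 is floored at zero, with a warning
  expect_warning(cl0 <- intrinsic_clearance(5000, 100, 570, 375),
                 "floored")
  expect_identical(cl0, 0)
  expect_error(intrinsic_clearance(-1, 746, 570, 375), "non-negative")
})

test_that("hepatic extraction and bioavailability follow the
           well-stirred liver model", {
  expect_equal(hepatic_extraction(0, 0.13, 80), 0)
  expect_equal(hepatic_extraction(746, 0.13, 80),
               746 * 0.13 / (80 + 746 * 0.13), tolerance = 1e-12)
  expect_equal(hepatic_extraction(746, 0.13, 80), 0.5480,
               tolerance = 1e-4)
  expect_equal(hepatic_extraction(1e12, 0.13, 80), 1, tolerance = 1e-6)
  expect_equal(hepatic_bioavailability(746, 0.13, 80),
               1 - 0.5480, tolerance = 1e-4)
})

test_that("inverse-Gaussian input integrates to the bioavailable dose
           and has the stated mean", {
  rp <- ritonavir_params()
  total <- integrate(function(t) inverse_gaussian_input(t, 100, rp),
                     0, Inf, rel.tol = 1e-9)$value
  expect_equal(total, rp$bioavailable_fraction * 100, tolerance = 1e-6)
  mean_t <- integrate(function(t)
    t * inverse_gaussian_density(t, rp$mean_absorption_time,
                                 rp$mean_absorption_time / rp$input_shape),
    0, Inf, rel.tol = 1e-9)$value
  expect_equal(mean_t, rp$mean_absorption_time, tolerance = 1e-6)
  expect_identical(inverse_gaussian_density(0, 2, 4), 0)
  expect_true(all(inverse_gaussian_density(c(0.1, 1, 10), 2, 4) > 0))
  expect_error(inverse_gaussian_density(1, -2, 4), "positive")
})

test_that("kin stimulation is a bounded Emax multiplier", {
  expect_identical(kin_stimulation(0, 284), 1)
  expect_equal(kin_stimulation(284, 284), 1.5)
  expect_equal(kin_stimulation(1e12, 284), 2, tolerance = 1e-9)
  s <- kin_stimulation(seq(0, 2000, by = 10), 284)
  expect_true(all(diff(s) > 0) && all(s >= 1) && all(s < 2))
})

test_that("TSP-1 turnover: steady state at baseline, derived rates,
           analytic approach to the stimulated steady state", {
  tp <- tsp1_params()
  expect_equal(tp$kin0, 43.8 / 233, tolerance = 1e-12)
  expect_equal(tp$kout, 1 / 233, tolerance = 1e-12)
  expect_equal(tp$kin0, tp$baseline * tp$kout)  # exact constraint
  expect_equal(tsp1_rhs(43.8, 0, tp), 0)
  # constant paclitaxel at the EC50: integrate and compare with the
  # closed-form exponential approach to 1.5 x baseline
  rhs <- function(t, y, p) list(tsp1_rhs(y, 284, tp))
  times <- seq(0, 10 * 233, by = 10)
  sol <- deSolve::lsoda(c(tsp = tp$baseline), times, rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  analytic <- 1.5 * tp$baseline +
    (tp$baseline - 1.5 * tp$baseline) * exp(-tp$kout * times)
  expect_equal(unname(sol[, 2]), analytic, tolerance = 1e-6)
  expect_equal(unname(sol[nrow(sol), 2]), 65.7, tolerance = 1e-3)
})

test_that("ritonavir reference derivatives: rest state, mass
           conservation, terminal monoexponential slope", {
  rp <- ritonavir_params()
  doses <- data.frame(time = 0, amount_mg = 100)
  expect_identical(ritonavir_rhs(c(0, 0), 5, rp, NULL), c(0, 0))

  # no elimination: everything that enters stays
  rp0 <- ritonavir_params(clearance = 1e-9)
  rhs <- function(t, y, p) list(ritonavir_rhs(y, t, rp0, doses))
  sol <- deSolve::lsoda(c(0, 0), seq(0, 200, by = 5), rhs, NULL,
                        rtol = 1e-10, atol = 1e-10)
  expect_equal(sum(sol[nrow(sol), 2:3]), 100 * 1000 *
                 rp0$bioavailable_fraction, tolerance = 1e-4)

  # collapse to one compartment: terminal log-slope is -CL/Vc
  rp1 <- ritonavir_params(clearance = 10, vc = 50, q_inter = 1e-9)
  rhs1 <- function(t, y, p) list(ritonavir_rhs(y, t, rp1, doses))
  sol1 <- deSolve::lsoda(c(0, 0), c(0, 60, 70), rhs1, NULL,
                         rtol = 1e-10, atol = 1e-10)
  slope <- unname((log(sol1[3, 2]) - log(sol1[2, 2])) / 10)
  expect_equal(slope, -10 / 50, tolerance = 1e-3)
})

test_that("IV paclitaxel plug-in: closed-form AUC, saturable limit,
           rest state", {
  expect_identical(
    iv_paclitaxel_rhs(c(0, 0, 0), 1, iv_paclitaxel_params(), NULL),
    c(0, 0, 0))
  # linear mode, near-bolus: AUC to infinity equals dose / CL
  ivp <- iv_paclitaxel_params(elimination = "linear", clearance = 20)
  inf <- data.frame(time = 0, duration = 0.01, amount_mg = 100)
  prof <- simulate_iv(inf, ivp, seq(0, 2000, by = 1))
  expect_equal(prof$auc_pac[nrow(prof)], 100 * 1000 / 20,
               tolerance = 1e-3)
  # saturable mode far below km behaves linearly with CL = vmax/km:
  # the two profiles agree within 1%
  ivs <- iv_paclitaxel_params(elimination = "saturable",
                              vmax = 2e7, km = 1e6)
  ivl <- iv_paclitaxel_params(elimination = "linear",
                              clearance = 2e7 / 1e6)
  ts <- seq(0, 48, by = 0.5)
  ps <- simulate_iv(inf, ivs, ts)$conc_pac[-1]
  pl <- simulate_iv(inf, ivl, ts)$conc_pac[-1]
  expect_lt(max(abs(ps - pl) / pl), 0.01)
  expect_error(
    iv_paclitaxel_rhs(c(0, 0, 0), 0.5, ivp,
                      data.frame(time = 0, duration = -1,
                                 amount_mg = 1)),
    "duration")
})

test_that("the compiled solver reproduces the R reference right-hand
           sides", {
  cfg <- pax_cfg
  reg <- single_dose_regimen(100, "solution", by = 0.5)
  prof_c <- simulate_typical(reg, cfg, rtol = 1e-10, atol = 1e-12)

  # compose the same system from the exported R reference RHS functions
  rtv_doses <- reg$rtv
  doses <- data.frame(time = reg$pac$time,
                      alpha = cfg$paclitaxel$alpha_first_dose,
                      beta = cfg$paclitaxel$beta_solution,
                      amount_ug = reg$pac$amount_mg * 1000)
  rhs <- function(t, y, p) {
    drtv <- ritonavir_rhs(y[1:2], t, cfg$ritonavir, rtv_doses)
    crtv_fn <- function(tt) y[1] / cfg$ritonavir$vc
    dpac <- oral_paclitaxel_rhs(y[3:6], t, cfg$paclitaxel, cfg$physio,
                                crtv_fn, doses)
    dtsp <- tsp1_rhs(y[7], y[5] / cfg$paclitaxel$vc, cfg$tsp1)
    list(c(drtv, dpac, dtsp))
  }
  y0 <- c(rtv_c = 0, rtv_p = 0, gut = 0, liver = 0, central = 0,
          peripheral = 0, tsp1 = cfg$tsp1$baseline)
  ev <- data.frame(var = 3, time = 0.5, value = 100 * 1000,
                   method = "add")
  times <- sort(unique(c(reg$grid, 0, 0.5)))
  sol <- deSolve::lsoda(y0, times, rhs, NULL, rtol = 1e-10,
                        atol = 1e-12, events = list(data = ev))
  ref_pac <- sol[match(reg$grid, sol[, 1]), 6] / cfg$paclitaxel$vc
  ref_tsp <- sol[match(reg$grid, sol[, 1]), 8]
  expect_equal(prof_c$conc_pac, ref_pac, tolerance = 1e-6)
  expect_equal(prof_c$tsp1, ref_tsp, tolerance = 1e-8)
})

test_that("liver compartment reproduces the extraction-ratio algebra at
           steady state", {
  cfg <- pax_cfg
  pac <- cfg$paclitaxel; phy <- cfg$physio
  crtv <- 300  # constant ritonavir concentration
  clint <- intrinsic_clearance(crtv, pac$clint0, pac$imax, pac$ki)
  # one old dose with first-order (beta = 1) absorption: known input rate
  doses <- data.frame(time = 0, alpha = 2, beta = 1, amount_ug = NA)
  gut <- 5000; t <- 1
  rate_in <- weibull_absorption_rate(t, 2, 1) * gut
  # liver amount solving the steady-state balance with zero plasma level
  a_h <- rate_in * phy$liver_volume /
    (phy$hepatic_blood_flow + phy$fraction_unbound * clint)
  d <- oral_paclitaxel_rhs(c(gut, a_h, 0, 0), t, pac, phy,
                           function(tt) crtv, doses)
  expect_equal(d[2], 0, tolerance = 1e-9)
  # realized extraction = eliminated / input = the well-stirred ratio
  e_real <- phy$fraction_unbound * clint * (a_h / phy$liver_volume) /
    rate_in
  expect_equal(e_real,
               hepatic_extraction(clint, phy$fraction_unbound,
                                  phy$hepatic_blood_flow),
               tolerance = 1e-9)
})
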