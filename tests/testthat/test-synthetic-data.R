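# Synthetic trial generation emulating the three study designs.

test_that("the metronomic (study 3) template encodes the published
           design: twice-daily doses 7 h apart, 200 mg/day ritonavir,
           studied dose levels only", {
  spec <- trial_design_spec("study3", n_subjects = 9, n_days = 2)
  trial <- generate_trial(spec, pax_cfg, seed = 41)
  expect_silent(validate_dataset(trial))
  expect_equal(length(unique(trial$ID)), 9)
  sub <- trial[trial$ID == 1, ]
  pac_doses <- sub[sub$EVID == 1L & sub$CMT == "pac", ]
  expect_equal(pac_doses$TIME, c(0, 7, 24, 31))
  expect_equal(pac_doses$DDI, c(1L, 2L, 1L, 2L))
  rtv_doses <- sub[sub$EVID == 1L & sub$CMT == "rtv", ]
  expect_equal(sum(rtv_doses$AMT[rtv_doses$TIME < 24]), 200)
  expect_error(trial_design_spec("study3", daily_dose_mg = 25),
               "studied levels")
  # capsule at 5-40 mg/day, tablet at 50-60; 40 goes to both
  forms <- vapply(split(trial, trial$ID), function(s)
    s$FORM[s$EVID == 1L & s$CMT == "pac"][1], character(1))
  daily <- vapply(split(trial, trial$ID), function(s)
    sum(s$AMT[s$EVID == 1L & s$CMT == "pac" & s$TIME < 24]),
    numeric(1))
  expect_true(all(forms[daily < 40] == "capsule"))
  expect_true(all(forms[daily > 40] == "tablet"))
})

test_that("the weekly crossover (study 2) template alternates
           formulation order across subjects at 30 mg", {
  spec <- trial_design_spec("study2")
  trial <- generate_trial(spec, pax_cfg, seed = 42)
  expect_equal(length(unique(trial$ID)), 4)
  f <- function(id) {
    s <- trial[trial$ID == id & trial$EVID == 1L & trial$CMT == "pac", ]
    expect_equal(s$TIME, c(0.5, 168.5))
    expect_equal(s$OCC, c(1L, 2L))
    expect_true(all(s$AMT == 30))
    s$FORM
  }
  expect_equal(f(1), c("solution", "capsule"))
  expect_equal(f(2), c("capsule", "solution"))
})

test_that("a zero-variability truth collapses the population to one
           subject profile", {
  spec <- trial_design_spec("study1", n_subjects = 4,
                            rtv_dose_mg = 100)
  cfg0 <- zero_re_config()
  trial <- generate_trial(spec, cfg0, seed = 43)
  obs <- trial[trial$EVID == 0L & trial$CMT == "pac" & trial$MDV == 0L, ]
  per_time <- split(obs$DV, obs$TIME)
  expect_true(all(vapply(per_time, function(x)
    diff(range(x)) < 1e-10, logical(1))))
})

test_that("TSP-1 records scatter around the baseline with the PD error
           CV when exposure is negligible, and never exceed the
           doubling bound under sustained exposure", {
  cfg <- zero_re_config(sigma_pd = 13.8)
  spec <- trial_design_spec("custom", n_subjects = 25,
                            daily_dose_mg = 0.001,
                            formulation = "capsule",
                            rtv_dose_mg = 100, n_days = 1,
                            pk_grid = c(1, 24),
                            pd_days = c(1, 3, 5, 7, 9, 11))
  trial <- generate_trial(spec, cfg, seed = 44)
  trial <- generate_pd_observations(trial, seed = 45)
  pd <- trial[trial$CMT == "tsp1", ]
  expect_equal(nrow(pd), 25 * 6)
  expect_equal(sd(pd$DV) / mean(pd$DV), 0.138, tolerance = 0.2)
  expect_equal(mean(pd$DV), 43.8, tolerance = 0.02)

  # sustained high exposure: approach but never exceed 2 x baseline
  reg <- build_regimen(list(pac_dose_mg = 500, formulation = "tablet",
                            n_days = 30, doses_per_day = 2L,
                            rtv_dose_mg = 100,
                            grid = seq(0, 720, by = 1)))
  prof <- simulate_typical(reg, pax_cfg, rtol = 1e-6, atol = 1e-8)
  expect_true(all(prof$tsp1 < 2 * 43.8))
  expect_gt(max(prof$tsp1), 1.3 * 43.8)

  # an empty sampling-day list adds nothing
  expect_identical(generate_pd_observations(trial, pd_days = numeric(0)),
                   trial)
})

test_that("generation is deterministic given the seed and datasets pass
           validation", {
  spec <- mixed_single_dose_spec(3)
  t1 <- generate_trial(spec, pax_cfg, seed = 46)
  t2 <- generate_trial(spec, pax_cfg, seed = 46)
  attr(t1, "truth") <- attr(t2, "truth") <- NULL
  expect_identical(t1, t2)
})
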