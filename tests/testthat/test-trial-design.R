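# Regimen construction, occasion/daily-dose bookkeeping, dataset
# reading/writing/validation.

test_that("the recommended phase II design expands to 42 tablet doses
           with the second daily dose 7 h after the first", {
  reg <- build_regimen(rp2d_design())
  expect_equal(nrow(reg$pac), 42)
  expect_equal(reg$pac$occasion, 1:42)
  expect_equal(reg$pac$ddi, rep(c(1L, 2L), 21))
  day <- rep(0:20 * 24, each = 2)
  expect_equal(reg$pac$time, day + rep(c(0, 7), 21))
  expect_true(all(reg$pac$formulation == "tablet"))
  expect_equal(nrow(reg$rtv), 42)
})

test_that("a single-dose solution design has one occasion and the
           ritonavir lead is encoded as non-negative times", {
  reg <- build_regimen(list(pac_dose_mg = 100, formulation = "solution",
                            rtv_dose_mg = 100, rtv_lead_h = 0.5))
  expect_equal(nrow(reg$pac), 1)
  expect_equal(reg$pac$occasion, 1L)
  expect_equal(reg$pac$time, 0.5)
  expect_equal(reg$rtv$time, 0)
  expect_true(all(reg$grid >= 0))
})

test_that("an empty design yields an empty, valid regimen and the
           builder is invariant to field order", {
  empty <- build_regimen(list())
  expect_s3_class(empty, "regimen")
  expect_equal(nrow(empty$pac), 0)
  d1 <- list(pac_dose_mg = 20, formulation = "tablet", n_days = 2,
             doses_per_day = 2L, rtv_dose_mg = 100)
  d2 <- d1[c(4, 2, 5, 1, 3)]
  expect_identical(build_regimen(d1), build_regimen(d2))
  expect_error(build_regimen(list(pac_dose_mg = 10,
                                  pac_times = c(1, 1))),
               "overlapping")
  expect_error(build_regimen(list(pac_dose_mg = 10, oops = 1)),
               "unknown design field")
})

test_that("daily-dose index marks the first dose of each 24-h block", {
  expect_equal(assign_daily_dose_index(c(0, 7, 24, 31, 48)),
               c(1L, 2L, 1L, 2L, 1L))
  # unordered input, and third doses capped at index 2
  expect_equal(assign_daily_dose_index(c(31, 0, 7, 14, 24)),
               c(2L, 1L, 2L, 2L, 1L))
  expect_equal(assign_daily_dose_index(numeric(0)), integer(0))
})

test_that("datasets round-trip through CSV exactly", {
  trial <- generate_trial(mixed_single_dose_spec(4), pax_cfg, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(trial, path)
  back <- read_dataset(path)
  attr(trial, "truth") <- NULL
  expect_equal(back, trial, tolerance = 0)
  # unknown columns are preserved opaquely
  trial$EXTRA <- seq_len(nrow(trial)) * 1.5
  write_dataset(trial, path)
  expect_equal(read_dataset(path)$EXTRA, trial$EXTRA)
})

test_that("validation reports offending rows for each contract
           violation", {
  trial <- generate_trial(mixed_single_dose_spec(2), pax_cfg, seed = 3)
  attr(trial, "truth") <- NULL

  bad <- trial
  bad$AMT[bad$EVID == 1L][1] <- NA
  err <- tryCatch(validate_dataset(bad), error = identity)
  expect_s3_class(err, "pax_validation_error")
  expect_match(conditionMessage(err), "dose row without positive AMT")
  expect_match(conditionMessage(err),
               paste0("rows ", which(bad$EVID == 1L)[1]))

  bad2 <- trial
  bad2$TIME[2] <- -1
  expect_error(validate_dataset(bad2), "negative TIME",
               class = "pax_validation_error")

  bad3 <- trial[order(-trial$TIME), ]
  expect_error(validate_dataset(bad3), "not sorted",
               class = "pax_validation_error")

  expect_error(validate_dataset(trial[, -match("OCC", names(trial))]),
               "missing mandatory column",
               class = "pax_validation_error")

  # a flagged-missing observation without a value is accepted
  ok <- trial
  i <- which(ok$EVID == 0L)[1]
  ok$DV[i] <- NA; ok$MDV[i] <- 1L
  expect_silent(validate_dataset(ok))
})

test_that("occasions number paclitaxel doses sequentially and
           observations inherit the most recent dose's occasion,
           independently per subject", {
  reg <- build_regimen(rp2d_design(n_days = 7))
  ds <- data.frame(ID = 1, TIME = reg$pac$time, EVID = 1L, CMT = "pac",
                   AMT = reg$pac$amount_mg, DV = NA_real_, MDV = 1L,
                   OCC = 0L, FORM = "tablet", DDI = reg$pac$ddi)
  obs <- data.frame(ID = 1, TIME = c(0.5, 8, 30), EVID = 0L,
                    CMT = "pac", AMT = NA_real_, DV = 1, MDV = 0L,
                    OCC = 0L, FORM = "", DDI = NA_integer_)
  two <- rbind(ds, obs)
  two <- rbind(two, transform(two, ID = 2))
  two <- two[order(two$ID, two$TIME, -two$EVID), ]
  out <- assign_occasions(two)
  for (id in 1:2) {
    d <- out[out$ID == id, ]
    expect_equal(d$OCC[d$EVID == 1L], 1:14)
    # 0.5 h follows dose 1, 8 h follows dose 2 (7 h), 30 h dose 3 (24 h)
    expect_equal(d$OCC[d$EVID == 0L], c(1L, 2L, 3L))
  }
  # single dose: every observation sits in occasion 1
  one <- rbind(ds[1, ], obs)
  expect_true(all(assign_occasions(one)$OCC == 1L))
})
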