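# Synthetic virtual trials emulating the three early-phase study
# designs, so every analysis stage is testable without clinical data:
#   study1  single 100 mg drinking-solution dose, ritonavir (100 or
#           200 mg) 30 min before paclitaxel, n = 17
#   study2  30 mg once weekly for two weeks, solution/capsule
#           crossover, ritonavir 100 mg 30 min before, n = 4
#   study3  low-dose metronomic twice-daily dosing with a 7-h
#           interval; capsule daily doses 5-40 mg, tablet 40-60 mg;
#           ritonavir 200 mg/day given as 100 mg with each paclitaxel
#           dose; TSP-1 sampled on days 1, 2, 8 and on day 1 of the
#           following cycles; n = 37
# The rich 0-24 h PK sampling grid is a fixture convention chosen to
# resolve the ~2 h Tmax.

PK_GRID <- c(0, 0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 10, 24)
STUDY3_CAPSULE_DAILY <- c(5, 10, 15, 20, 30, 40)
STUDY3_TABLET_DAILY <- c(40, 50, 60)

#' Specify a synthetic trial design
#'
#' Templates emulate the three source study designs (see the package
#' vignette); `"custom"` designs describe one arm explicitly, with
#' per-subject recycling of `daily_dose_mg` and `formulation` so mixed
#' designs (e.g. solution and capsule arms) can be generated.
#'
#' @param template `"study1"`, `"study2"`, `"study3"` or `"custom"`.
#' @param n_subjects Number of subjects (template defaults: 17, 4, 37).
#' @param daily_dose_mg Daily dose(s), recycled across subjects. For
#'   templated studies the values must come from the studied dose
#'   levels. `custom` requires it.
#' @param formulation Formulation(s), recycled across subjects
#'   (`custom` only; templates fix their formulations).
#' @param doses_per_day,interval_h,n_days Dosing schedule (`custom`;
#'   study 3 uses twice daily, 7 h apart).
#' @param rtv_dose_mg Ritonavir dose per administration (`custom`).
#' @param rtv_lead_h Ritonavir lead time before paclitaxel (h).
#' @param pk_grid PK sampling times (h after the first daily dose).
#' @param pd_days Days with a TSP-1 sample (1-based; sampled pre-dose),
#'   `NULL` for none.
#' @param ritonavir_sampled Logical, recycled per subject: whether
#'   ritonavir concentrations are sampled for that subject.
#' @return A list of class `trial_design_spec`.
#' @export
trial_design_spec <- function(template = c("study1", "study2", "study3",
                                           "custom"),
                              n_subjects = NULL, daily_dose_mg = NULL,
                              formulation = NULL, doses_per_day = NULL,
                              interval_h = 7, rtv_dose_mg = NULL,
                              rtv_lead_h = NULL, n_days = NULL,
                              pk_grid = PK_GRID, pd_days = NULL,
                              ritonavir_sampled = TRUE) {
  template <- match.arg(template)
  if (template == "study1") {
    n_subjects <- n_subjects %||% 17L
    daily_dose_mg <- daily_dose_mg %||% 100
    if (!all(daily_dose_mg == 100))
      stop("study1 used a single 100 mg dose", call. = FALSE)
    formulation <- "solution"; doses_per_day <- 1L; n_days <- 1L
    rtv_dose_mg <- rtv_dose_mg %||% c(100, 200)  # recycled per subject
    rtv_lead_h <- rtv_lead_h %||% 0.5
  } else if (template == "study2") {
    n_subjects <- n_subjects %||% 4L
    daily_dose_mg <- daily_dose_mg %||% 30
    if (!all(daily_dose_mg == 30))
      stop("study2 used 30 mg once weekly", call. = FALSE)
    formulation <- NULL  # crossover, set per dose below
    doses_per_day <- 1L; n_days <- 1L
    rtv_dose_mg <- rtv_dose_mg %||% 100
    rtv_lead_h <- rtv_lead_h %||% 0.5
  } else if (template == "study3") {
    n_subjects <- n_subjects %||% 37L
    daily_dose_mg <- daily_dose_mg %||%
      c(STUDY3_CAPSULE_DAILY, STUDY3_TABLET_DAILY)
    ok <- daily_dose_mg %in% STUDY3_CAPSULE_DAILY |
      daily_dose_mg %in% STUDY3_TABLET_DAILY
    if (!all(ok))
      stop("study3 daily doses must come from the studied levels ",
           "(capsule 5-40, tablet 40-60 mg)", call. = FALSE)
    doses_per_day <- 2L
    n_days <- n_days %||% (if (is.null(pd_days)) 1L else
      max(pd_days))
    rtv_dose_mg <- rtv_dose_mg %||% 100  # 200 mg/day split over doses
    rtv_lead_h <- rtv_lead_h %||% 0
    pd_days <- pd_days %||% NULL
  } else {
    if (is.null(daily_dose_mg))
      stop("custom designs need daily_dose_mg", call. = FALSE)
    n_subjects <- n_subjects %||% length(daily_dose_mg)
    formulation <- formulation %||% "tablet"
    doses_per_day <- doses_per_day %||% 1L
    n_days <- n_days %||% 1L
    rtv_lead_h <- rtv_lead_h %||% 0
  }
  stopifnot(n_subjects > 0)
  structure(list(template = template, n_subjects = as.integer(n_subjects),
                 daily_dose_mg = daily_dose_mg,
                 formulation = formulation,
                 doses_per_day = as.integer(doses_per_day %||% 1L),
                 interval_h = interval_h,
                 rtv_dose_mg = rtv_dose_mg, rtv_lead_h = rtv_lead_h,
                 n_days = as.integer(n_days),
                 pk_grid = pk_grid, pd_days = pd_days,
                 ritonavir_sampled = ritonavir_sampled),
            class = "trial_design_spec")
}

# Per-subject regimen for a design spec.
subject_regimen <- function(spec, i) {
  rtv_mg <- rep(spec$rtv_dose_mg %||% 100,
                length.out = spec$n_subjects)[i]
  if (spec$template == "study2") {
    forms <- if (i %% 2 == 1) c("solution", "capsule")
    else c("capsule", "solution")
    design <- list(pac_dose_mg = 30, formulation = forms,
                   pac_times = c(0, 168), rtv_times = c(-0.5, 167.5),
                   rtv_dose_mg = rtv_mg, rtv_lead_h = 0.5,
                   grid = c(0.5 + spec$pk_grid, 168.5 + spec$pk_grid))
    return(build_regimen(design))
  }
  daily <- rep(spec$daily_dose_mg, length.out = spec$n_subjects)[i]
  if (spec$template == "study3") {
    # 40 mg/day was studied with both formulations; alternate
    form <- if (daily >= 50 || (daily == 40 && i %% 2 == 0))
      "tablet" else "capsule"
  } else {
    form <- rep(spec$formulation %||% "tablet",
                length.out = spec$n_subjects)[i]
  }
  per_adm <- daily / spec$doses_per_day
  off <- max(spec$rtv_lead_h %||% 0, 0)
  design <- list(pac_dose_mg = per_adm, formulation = form,
                 n_days = spec$n_days, doses_per_day = spec$doses_per_day,
                 interval_h = spec$interval_h,
                 rtv_dose_mg = rtv_mg, rtv_lead_h = spec$rtv_lead_h,
                 rtv_doses_per_day = spec$doses_per_day,
                 grid = off + spec$pk_grid)
  build_regimen(design)
}

#' Generate a synthetic PK trial dataset
#'
#' For each subject: draws the between-subject and per-occasion random
#' effects, simulates the coupled system under the subject's regimen,
#' applies proportional residual error and emits dose and observation
#' records. Pre-dose paclitaxel samples (true concentration zero) are
#' kept with the missing flag set, since the proportional error model
#' is degenerate there. Deterministic given `seed`. The generating
#' parameters and per-subject random effects are attached as the
#' `"truth"` attribute (the sidecar used by recovery tests).
#'
#' @param spec A [trial_design_spec()].
#' @param config Generating ("truth") configuration; defaults to the
#'   shipped population estimates.
#' @param seed Integer seed.
#' @param absorption,rtol,atol Solver options.
#' @return A validated study dataset (data frame) with attribute
#'   `truth`.
#' @export
generate_trial <- function(spec, config = default_config(),
                           seed = NULL, absorption = "hazard",
                           rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(spec, "trial_design_spec"))
  if (!is.null(seed)) set.seed(seed)
  sigma_pk <- config$random_effects$sigma_prop_pk / 100
  rtv_sampled <- rep(spec$ritonavir_sampled,
                     length.out = spec$n_subjects)
  rows <- list(); individuals <- list()
  for (i in seq_len(spec$n_subjects)) {
    reg <- subject_regimen(spec, i)
    ind <- sample_individual(config$random_effects,
                             n_occasions = nrow(reg$pac))
    individuals[[i]] <- ind
    prof <- simulate_profile(reg, config, grid = sort(unique(c(0, reg$grid))),
                             individual = ind, absorption = absorption,
                             rtol = rtol, atol = atol)
    at <- match(reg$grid, prof$time)
    pred <- prof$conc_pac[at]
    dv <- apply_residual_error(pred, sigma_pk)
    mdv <- as.integer(pred <= 0)
    dv[mdv == 1L] <- NA_real_
    sub <- rbind(
      data.frame(ID = i, TIME = reg$pac$time, EVID = 1L, CMT = "pac",
                 AMT = reg$pac$amount_mg, DV = NA_real_, MDV = 1L,
                 OCC = reg$pac$occasion, FORM = reg$pac$formulation,
                 DDI = reg$pac$ddi),
      if (nrow(reg$rtv))
        data.frame(ID = i, TIME = reg$rtv$time, EVID = 1L, CMT = "rtv",
                   AMT = reg$rtv$amount_mg, DV = NA_real_, MDV = 1L,
                   OCC = 1L, FORM = "", DDI = NA_integer_),
      data.frame(ID = i, TIME = reg$grid, EVID = 0L, CMT = "pac",
                 AMT = NA_real_, DV = dv, MDV = mdv, OCC = 1L,
                 FORM = "", DDI = NA_integer_),
      if (rtv_sampled[i]) {
        rpred <- prof$conc_rtv[at]
        rdv <- apply_residual_error(rpred, sigma_pk)
        rmdv <- as.integer(rpred <= 0)
        rdv[rmdv == 1L] <- NA_real_
        data.frame(ID = i, TIME = reg$grid, EVID = 0L, CMT = "rtv",
                   AMT = NA_real_, DV = rdv, MDV = rmdv, OCC = 1L,
                   FORM = "", DDI = NA_integer_)
      })
    sub <- sub[order(sub$TIME, -sub$EVID), ]
    rows[[i]] <- sub
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- assign_occasions(out)
  validate_dataset(out)
  attr(out, "truth") <- list(spec = spec, config = config,
                             individuals = individuals, seed = seed)
  out
}

#' Add TSP-1 observations to a generated trial
#'
#' Re-simulates each subject at the pharmacodynamic sampling days
#' (pre-dose) using the stored true random effects and appends TSP-1
#' records with proportional residual error, in
#' ng/mL per 10^6 platelets. With an empty sampling-day list the
#' dataset is returned unchanged.
#'
#' @param trial A dataset from [generate_trial()] (must carry its
#'   `truth` attribute).
#' @param pd_days Sampling days (1-based); defaults to the design
#'   spec's `pd_days`.
#' @param seed Optional integer seed for the residual draws.
#' @return The dataset with appended `tsp1` observation rows and an
#'   updated `truth` attribute.
#' @export
generate_pd_observations <- function(trial, pd_days = NULL,
                                     seed = NULL) {
  truth <- attr(trial, "truth")
  if (is.null(truth))
    stop("trial lacks its `truth` attribute; regenerate it with ",
         "generate_trial()", call. = FALSE)
  spec <- truth$spec; config <- truth$config
  pd_days <- pd_days %||% spec$pd_days
  if (!length(pd_days)) return(trial)
  if (!is.null(seed)) set.seed(seed)
  sigma_pd <- config$random_effects$sigma_prop_pd / 100
  pd_times <- (pd_days - 1) * 24
  rows <- list()
  for (i in seq_len(spec$n_subjects)) {
    reg <- subject_regimen(spec, i)
    ind <- truth$individuals[[i]]
    prof <- simulate_profile(reg, config,
                             grid = sort(unique(c(0, pd_times))),
                             individual = ind, rtol = 1e-6, atol = 1e-8)
    pred <- prof$tsp1[match(pd_times, prof$time)]
    rows[[i]] <- data.frame(ID = i, TIME = pd_times, EVID = 0L,
                            CMT = "tsp1", AMT = NA_real_,
                            DV = apply_residual_error(pred, sigma_pd),
                            MDV = 0L, OCC = 1L, FORM = "",
                            DDI = NA_integer_)
  }
  out <- rbind(trial, do.call(rbind, rows))
  out <- out[order(out$ID, out$TIME, -out$EVID), ]
  rownames(out) <- NULL
  out <- assign_occasions(out)
  validate_dataset(out)
  attr(out, "truth") <- truth
  out
}
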