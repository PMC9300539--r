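# Forward simulation: typical-value and population profiles, residual
# error, and non-compartmental exposure metrics.

# Resolve per-dose absorption parameters and gut-bioavailable amounts:
# ALPHA by daily-dose index, BETA by formulation, relative gut
# bioavailability by formulation x daily-dose index x exp(eta_BSV +
# eta_BOV(occasion)).
resolve_pac_doses <- function(pac, params, eta = NULL, bov = NULL) {
  if (is.null(pac) || !nrow(pac))
    return(data.frame(time = numeric(0), alpha = numeric(0),
                      beta = numeric(0), amount_ug = numeric(0)))
  if (!all(pac$formulation %in% c("solution", "capsule", "tablet")))
    stop("unknown formulation code", call. = FALSE)
  e <- function(nm) {
    if (is.null(eta) || !nm %in% names(eta)) return(0)
    unname(eta[[nm]])
  }
  alpha <- ifelse(pac$ddi == 1L, params$alpha_first_dose,
                  params$alpha_second_dose) * exp(e("alpha"))
  beta <- ifelse(pac$formulation == "solution", params$beta_solution,
                 params$beta_asd)
  rf_form <- c(solution = params$rf_solution,
               tablet = params$rf_tablet,
               capsule = params$rf_capsule)[pac$formulation]
  bov_term <- if (is.null(bov)) 0 else bov[pac$occasion]
  rf <- rf_form * ifelse(pac$ddi == 2L, params$rf_second_over_first, 1) *
    exp(e("rf_gut") + bov_term)
  data.frame(time = pac$time, alpha = alpha, beta = beta,
             amount_ug = pac$amount_mg * 1000 * unname(rf))
}

# Apply lognormal random effects to the population parameter lists.
apply_individual <- function(pac, tsp, individual) {
  if (is.null(individual)) return(list(pac = pac, tsp = tsp))
  eta <- individual$eta
  g <- function(nm) {
    if (is.null(eta) || !nm %in% names(eta)) return(1)
    exp(unname(eta[[nm]]))
  }
  pac$clint0 <- pac$clint0 * g("clint0")
  pac$vc <- pac$vc * g("vc")
  tsp <- tsp1_params(ec50 = tsp$ec50,
                     baseline = tsp$baseline * g("ebase"),
                     turnover_time = tsp$turnover_time)
  list(pac = pac, tsp = tsp)
}

#' Simulate a concentration-time profile for one subject
#'
#' Solves the full system for a regimen: ritonavir PK feeds the
#' time-varying intrinsic-clearance inhibition of the oral paclitaxel
#' model, whose plasma concentration drives the TSP-1 turnover state.
#' With `individual = NULL` this is the typical-value
#' (population-parameter) simulation; otherwise the individual's
#' lognormal random effects are applied (BSV on the Weibull scale,
#' intrinsic clearance, central volume, relative gut bioavailability
#' and TSP-1 baseline; BOV on relative gut bioavailability per
#' occasion).
#'
#' @param regimen A [build_regimen()] object.
#' @param config A [default_config()]-style configuration.
#' @param grid Output times (h); defaults to the regimen's grid.
#' @param individual `NULL`, or a [sample_individual()] object.
#' @param absorption Weibull implementation, see [solve_pkpd()].
#' @param rtol,atol Solver tolerances.
#' @return Data frame as returned by [solve_pkpd()].
#' @export
simulate_profile <- function(regimen, config, grid = NULL,
                             individual = NULL,
                             absorption = c("hazard", "input"),
                             rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(regimen, "regimen"))
  absorption <- match.arg(absorption)
  grid <- grid %||% regimen$grid
  if (!length(grid)) stop("no output grid supplied", call. = FALSE)
  if (nrow(regimen$pac) > 0 && nrow(regimen$rtv) == 0)
    warning("oral paclitaxel simulated without ritonavir doses: ",
            "intrinsic clearance stays uninhibited")
  ind <- apply_individual(config$paclitaxel, config$tsp1, individual)
  doses <- resolve_pac_doses(regimen$pac, ind$pac,
                             eta = individual$eta,
                             bov = individual$bov)
  solve_pkpd(doses, regimen$rtv, ind$pac, config$physio,
             config$ritonavir, ind$tsp, times = grid,
             absorption = absorption, rtol = rtol, atol = atol)
}

#' @rdname simulate_profile
#' @export
simulate_typical <- function(regimen, config, grid = NULL,
                             absorption = c("hazard", "input"),
                             rtol = 1e-8, atol = 1e-10) {
  simulate_profile(regimen, config, grid = grid, individual = NULL,
                   absorption = match.arg(absorption),
                   rtol = rtol, atol = atol)
}

#' Draw individual random effects
#'
#' Samples the between-subject effects (`alpha`, `clint0`, `vc`,
#' `rf_gut`, `ebase`) and one between-occasion effect on relative gut
#' bioavailability per occasion, all normal on the log scale with
#' standard deviations from the CV% entries of the
#' [random_effects_spec()] (conversion per [cv_to_omega()]). With all
#' CVs zero the individual equals the typical subject.
#'
#' @param spec A [random_effects_spec()].
#' @param n_occasions Number of dosing occasions (BOV draws).
#' @param seed Optional integer seed for reproducible draws.
#' @param cv_method Conversion convention, see [cv_to_omega()].
#' @return An object of class `individual_params`: list with named
#'   vector `eta` and numeric `bov`.
#' @export
sample_individual <- function(spec, n_occasions = 1, seed = NULL,
                              cv_method = "linear") {
  stopifnot(inherits(spec, "random_effects_spec"), n_occasions >= 0)
  if (!is.null(seed)) set.seed(seed)
  om <- cv_to_omega(spec$bsv_cv, cv_method)
  eta <- c(rnorm(4) * om,
           ebase = rnorm(1) * cv_to_omega(spec$bsv_ebase_cv, cv_method))
  names(eta)[1:4] <- names(spec$bsv_cv)
  bov <- rnorm(n_occasions) * cv_to_omega(spec$bov_cv[["rf_gut"]],
                                          cv_method)
  structure(list(eta = eta, bov = bov), class = "individual_params")
}

#' Apply proportional residual error
#'
#' `obs = pred * (1 + eps)`, `eps ~ N(0, sigma^2)`. Zero predictions
#' stay zero; `sigma = 0` returns the predictions unchanged.
#'
#' @param pred Predicted values.
#' @param sigma_prop Proportional SD (e.g. 0.258 for 25.8 CV%).
#' @param seed Optional integer seed.
#' @return Perturbed observations.
#' @export
apply_residual_error <- function(pred, sigma_prop, seed = NULL) {
  stopifnot(sigma_prop >= 0)
  if (!is.null(seed)) set.seed(seed)
  pred * (1 + rnorm(length(pred)) * sigma_prop)
}

#' Exposure metrics of a simulated profile
#'
#' Computes Cmax (grid maximum with local quadratic refinement), Tmax
#' (relative to a stated dose time), AUC over the window (trapezoid on
#' the profile grid) and the cumulative time the concentration exceeds
#' a threshold (linear interpolation of the crossings).
#'
#' @param profile Data frame with a `time` column and the concentration
#'   column named by `conc_col`.
#' @param window Two-element window `[t0, t1]` (h); must be covered by
#'   the grid.
#' @param threshold Threshold (ng/mL) for the time-above metric;
#'   default 42.7 ng/mL (0.05 umol/L).
#' @param reference_dose_time Dose time Tmax is reported against.
#' @param conc_col Concentration column name.
#' @return List with `cmax` (ng/mL), `tmax` (h), `auc` (ug.h/L),
#'   `time_above` (h).
#' @export
pk_metrics <- function(profile, window = range(profile$time),
                       threshold = 42.7, reference_dose_time = 0,
                       conc_col = "conc_pac") {
  stopifnot(length(window) == 2, window[1] < window[2])
  if (window[1] < min(profile$time) - 1e-9 ||
      window[2] > max(profile$time) + 1e-9)
    stop("window outside the profile grid", call. = FALSE)
  keep <- profile$time >= window[1] - 1e-9 &
    profile$time <= window[2] + 1e-9
  t <- profile$time[keep]
  c <- profile[[conc_col]][keep]
  if (length(t) < 3) stop("window too sparse", call. = FALSE)

  i <- which.max(c)
  cmax <- c[i]; tmax <- t[i]
  if (i > 1 && i < length(c)) {
    # quadratic through the three points around the grid maximum
    x <- t[(i - 1):(i + 1)]; y <- c[(i - 1):(i + 1)]
    d21 <- (y[2] - y[1]) / (x[2] - x[1])
    d32 <- (y[3] - y[2]) / (x[3] - x[2])
    a <- (d32 - d21) / (x[3] - x[1])
    if (a < 0) {
      tv <- (x[1] + x[2]) / 2 - d21 / (2 * a)
      if (tv >= x[1] && tv <= x[3]) {
        # interpolating quadratic in Newton form
        cv <- y[1] + d21 * (tv - x[1]) + a * (tv - x[1]) * (tv - x[2])
        if (cv >= cmax) { cmax <- cv; tmax <- tv }
      }
    }
  }
  auc <- sum(diff(t) * (head(c, -1) + c[-1]) / 2)

  above <- c > threshold
  time_above <- 0
  if (any(above)) {
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- c(1, head(ends, -1) + 1)
    for (k in which(runs$values)) {
      i0 <- starts[k]; i1 <- ends[k]
      t_in <- if (i0 == 1) t[1] else {
        # linear interpolation of the upward crossing
        t[i0 - 1] + (threshold - c[i0 - 1]) /
          (c[i0] - c[i0 - 1]) * (t[i0] - t[i0 - 1])
      }
      t_out <- if (i1 == length(t)) t[length(t)] else {
        t[i1] + (threshold - c[i1]) /
          (c[i1 + 1] - c[i1]) * (t[i1 + 1] - t[i1])
      }
      time_above <- time_above + (t_out - t_in)
    }
  }
  list(cmax = cmax, tmax = tmax - reference_dose_time, auc = auc,
       time_above = time_above)
}

#' Simulate a population of individual profiles
#'
#' Draws `n` individuals from the random-effects specification and
#' simulates each under the same regimen.
#'
#' @param regimen A [build_regimen()] object.
#' @param config Configuration list.
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @param grid Output times; defaults to the regimen grid.
#' @param absorption See [solve_pkpd()].
#' @param rtol,atol Solver tolerances.
#' @return Long data frame: `id` plus the [solve_pkpd()] columns.
#' @export
simulate_population <- function(regimen, config, n, seed = NULL,
                                grid = NULL,
                                absorption = c("hazard", "input"),
                                rtol = 1e-6, atol = 1e-8) {
  absorption <- match.arg(absorption)
  if (!is.null(seed)) set.seed(seed)
  n_occ <- max(1, nrow(regimen$pac))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ind <- sample_individual(config$random_effects, n_occasions = n_occ)
    prof <- simulate_profile(regimen, config, grid = grid,
                             individual = ind, absorption = absorption,
                             rtol = rtol, atol = atol)
    out[[i]] <- cbind(id = i, prof)
  }
  do.call(rbind, out)
}
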