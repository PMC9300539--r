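#' Physiological constants for the well-stirred liver model
#'
#' Fixed physiological quantities used by the hepatic first-pass model:
#' hepatic blood flow, liver volume and the unbound fraction of
#' paclitaxel in plasma. Defaults are the literature values the model
#' fixes them to (80 L/h, 1 L, 0.13).
#'
#' @param hepatic_blood_flow Hepatic blood flow Q_H (L/h).
#' @param liver_volume Liver volume V_H (L).
#' @param fraction_unbound Unbound fraction of paclitaxel (0, 1].
#' @return A list of class `physio_constants`.
#' @export
physio_constants <- function(hepatic_blood_flow = 80,
                             liver_volume = 1,
                             fraction_unbound = 0.13) {
  stopifnot(hepatic_blood_flow > 0, liver_volume > 0)
  if (!(fraction_unbound > 0 && fraction_unbound <= 1))
    stop("fraction_unbound must be in (0, 1]", call. = FALSE)
  structure(list(hepatic_blood_flow = hepatic_blood_flow,
                 liver_volume = liver_volume,
                 fraction_unbound = fraction_unbound),
            class = "physio_constants")
}

#' Population parameters of the oral paclitaxel PK model
#'
#' Fixed-effect parameters of the gut/liver/central/peripheral model:
#' Weibull absorption scale (per daily-dose index) and shape (per
#' formulation), uninhibited intrinsic clearance with the ritonavir
#' inhibition parameters (Imax, KI), disposition parameters, and the
#' relative gut bioavailabilities of each formulation (drinking
#' solution as reference, fixed to 1) plus the second-versus-first
#' daily-dose bioavailability factor. Defaults are the final
#' population estimates.
#'
#' @param alpha_first_dose,alpha_second_dose Weibull scale (h) for the
#'   first and second daily dose.
#' @param beta_solution,beta_asd Weibull shape for the drinking
#'   solution and for the amorphous-solid-dispersion (tablet/capsule)
#'   formulations.
#' @param clint0 Uninhibited intrinsic hepatic clearance (L/h).
#' @param ki Ritonavir concentration of half-maximal inhibition (ng/mL).
#' @param imax Maximum inhibitory effect on intrinsic clearance (L/h);
#'   must not exceed `clint0`.
#' @param vc,vp Central and peripheral volumes (L).
#' @param q Inter-compartmental clearance (L/h).
#' @param rf_solution,rf_tablet,rf_capsule Relative gut bioavailability
#'   per formulation (solution is the reference, 1).
#' @param rf_second_over_first Relative bioavailability of the second
#'   daily dose versus the first.
#' @return A list of class `paclitaxel_params`.
#' @export
paclitaxel_params <- function(alpha_first_dose = 1.68,
                              alpha_second_dose = 1.97,
                              beta_solution = 2.53,
                              beta_asd = 3.57,
                              clint0 = 746,
                              ki = 375,
                              imax = 570,
                              vc = 128,
                              q = 33.4,
                              vp = 375,
                              rf_solution = 1,
                              rf_tablet = 0.97,
                              rf_capsule = 0.46,
                              rf_second_over_first = 0.59) {
  vals <- c(alpha_first_dose, alpha_second_dose, beta_solution, beta_asd,
            clint0, ki, imax, vc, q, vp,
            rf_solution, rf_tablet, rf_capsule, rf_second_over_first)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all paclitaxel parameters must be finite and positive",
         call. = FALSE)
  rfs <- c(rf_solution, rf_tablet, rf_capsule, rf_second_over_first)
  if (any(rfs > 2))
    stop("relative bioavailabilities must lie in (0, 2]", call. = FALSE)
  if (imax > clint0)
    stop("imax must not exceed clint0 (typical CLint would go negative)",
         call. = FALSE)
  structure(list(alpha_first_dose = alpha_first_dose,
                 alpha_second_dose = alpha_second_dose,
                 beta_solution = beta_solution,
                 beta_asd = beta_asd,
                 clint0 = clint0, ki = ki, imax = imax,
                 vc = vc, q = q, vp = vp,
                 rf_solution = rf_solution, rf_tablet = rf_tablet,
                 rf_capsule = rf_capsule,
                 rf_second_over_first = rf_second_over_first),
            class = "paclitaxel_params")
}

#' Population parameters of the ritonavir PK model
#'
#' Two-compartment disposition with first-order elimination and an
#' inverse-Gaussian density absorption input. The original literature
#' estimates for this model are not part of this package; the defaults
#' here are representative synthetic values and real analyses should
#' supply literature estimates through the configuration file (see
#' [read_config()] and the shipped
#' `external_models_synthetic.yaml` fixture).
#'
#' @param clearance Apparent clearance (L/h).
#' @param vc,vp Central and peripheral volumes (L).
#' @param q_inter Inter-compartmental clearance (L/h).
#' @param bioavailable_fraction Fraction of the dose reaching the
#'   systemic circulation, (0, 1].
#' @param mean_absorption_time Mean of the inverse-Gaussian input (h).
#' @param input_shape Relative variance (variance / mean^2) of the
#'   inverse-Gaussian input density.
#' @return A list of class `ritonavir_params`.
#' @export
ritonavir_params <- function(clearance = 20,
                             vc = 60,
                             q_inter = 6,
                             vp = 40,
                             bioavailable_fraction = 1,
                             mean_absorption_time = 2,
                             input_shape = 0.5) {
  vals <- c(clearance, vc, q_inter, vp, bioavailable_fraction,
            mean_absorption_time, input_shape)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all ritonavir parameters must be finite and positive",
         call. = FALSE)
  if (bioavailable_fraction > 1)
    stop("bioavailable_fraction must be in (0, 1]", call. = FALSE)
  structure(list(clearance = clearance, vc = vc, q_inter = q_inter,
                 vp = vp,
                 bioavailable_fraction = bioavailable_fraction,
                 mean_absorption_time = mean_absorption_time,
                 input_shape = input_shape),
            class = "ritonavir_params")
}

#' Parameters of the three-compartment IV paclitaxel plug-in model
#'
#' Standard mamillary three-compartment disposition with zero-order
#' infusion input and either linear or saturable (Michaelis-Menten)
#' elimination. Used only for simulation-based comparison of IV
#' schedules against oral low-dose metronomic dosing. Defaults are
#' representative synthetic values; supply literature estimates via
#' configuration for real comparisons.
#'
#' @param vc Central volume (L).
#' @param vp1,vp2 Peripheral volumes (L).
#' @param q1,q2 Inter-compartmental clearances (L/h).
#' @param elimination `"linear"` or `"saturable"`; exactly one mode is
#'   active.
#' @param clearance Linear clearance (L/h), required for
#'   `elimination = "linear"`.
#' @param vmax Maximum elimination rate (ug/h), saturable mode.
#' @param km Concentration of half-maximal elimination (ng/mL),
#'   saturable mode.
#' @return A list of class `iv_paclitaxel_params`.
#' @export
iv_paclitaxel_params <- function(vc = 10,
                                 vp1 = 30,
                                 vp2 = 275,
                                 q1 = 15,
                                 q2 = 15,
                                 elimination = c("saturable", "linear"),
                                 clearance = NULL,
                                 vmax = 30000,
                                 km = 500) {
  elimination <- match.arg(elimination)
  stopifnot(vc > 0, vp1 > 0, vp2 > 0, q1 > 0, q2 > 0)
  if (elimination == "linear") {
    if (is.null(clearance) || clearance <= 0)
      stop("linear elimination requires a positive clearance",
           call. = FALSE)
    vmax <- km <- NA_real_
  } else {
    stopifnot(vmax > 0, km > 0)
    clearance <- NA_real_
  }
  structure(list(vc = vc, vp1 = vp1, vp2 = vp2, q1 = q1, q2 = q2,
                 elimination = elimination, clearance = clearance,
                 vmax = vmax, km = km),
            class = "iv_paclitaxel_params")
}

#' Parameters of the TSP-1 turnover model
#'
#' Indirect-response model for thrombospondin-1: zero-order formation
#' `kin0` and first-order loss `kout = 1/turnover_time`, with
#' paclitaxel plasma concentration stimulating formation through an
#' Emax relationship (implicit maximum of a doubling). The derived
#' rates satisfy the steady-state constraint
#' `kin0 = baseline * kout` exactly so an untreated subject stays at
#' baseline.
#'
#' @param ec50 Paclitaxel concentration of half-maximal stimulation
#'   (ng/mL).
#' @param baseline Baseline TSP-1 (ng/mL per 10^6 platelets).
#' @param turnover_time TSP-1 turnover time (h); fixed to the platelet
#'   survival time of 233 h in the reference analysis.
#' @return A list of class `tsp1_params` with derived `kin0`, `kout`.
#' @export
tsp1_params <- function(ec50 = 284, baseline = 43.8, turnover_time = 233) {
  stopifnot(ec50 > 0, baseline > 0, turnover_time > 0)
  kout <- 1 / turnover_time
  structure(list(ec50 = ec50, baseline = baseline,
                 turnover_time = turnover_time,
                 kin0 = baseline * kout, kout = kout),
            class = "tsp1_params")
}

#' Variance components of the mixed-effects layer
#'
#' Between-subject (BSV) and between-occasion (BOV) variability,
#' expressed as CV%, for the lognormal random effects
#' `P_i = P * exp(eta_BSV + eta_BOV)`, together with the proportional
#' residual error SDs of the PK and PD layers. Defaults are the final
#' population estimates. Each paclitaxel dose administration counts as
#' one occasion.
#'
#' @param bsv_cv Named numeric: CV% of BSV for `alpha`, `clint0`, `vc`,
#'   `rf_gut`.
#' @param bov_cv Named numeric: CV% of BOV (only `rf_gut`).
#' @param sigma_prop_pk Proportional residual error of paclitaxel
#'   concentrations, CV%.
#' @param bsv_ebase_cv CV% of BSV on the TSP-1 baseline.
#' @param sigma_prop_pd Proportional residual error of TSP-1, CV%.
#' @return A list of class `random_effects_spec`.
#' @seealso [cv_to_omega()] for the CV%-to-omega convention.
#' @export
random_effects_spec <- function(bsv_cv = c(alpha = 35.1, clint0 = 25.1,
                                           vc = 53.8, rf_gut = 38.2),
                                bov_cv = c(rf_gut = 45.8),
                                sigma_prop_pk = 25.8,
                                bsv_ebase_cv = 28.2,
                                sigma_prop_pd = 13.8) {
  stopifnot(all(bsv_cv >= 0), all(bov_cv >= 0),
            sigma_prop_pk >= 0, bsv_ebase_cv >= 0, sigma_prop_pd >= 0)
  if (length(bsv_cv) > 0 && is.null(names(bsv_cv)))
    stop("bsv_cv entries must be named", call. = FALSE)
  need <- c("alpha", "clint0", "vc", "rf_gut")
  miss <- setdiff(need, names(bsv_cv))
  if (length(miss))
    bsv_cv[miss] <- 0
  if (!("rf_gut" %in% names(bov_cv)))
    bov_cv["rf_gut"] <- 0
  structure(list(bsv_cv = bsv_cv[need], bov_cv = bov_cv["rf_gut"],
                 sigma_prop_pk = sigma_prop_pk,
                 bsv_ebase_cv = bsv_ebase_cv,
                 sigma_prop_pd = sigma_prop_pd),
            class = "random_effects_spec")
}

#' Convert a CV% to a lognormal random-effect standard deviation
#'
#' The default (`"linear"`) uses the first-order reporting convention
#' omega = CV/100 common in nonlinear mixed-effects outputs; the exact
#' lognormal relation `omega = sqrt(log(1 + (CV/100)^2))` is available
#' with `method = "lognormal"`.
#'
#' @param cv_percent Coefficient of variation in percent.
#' @param method `"linear"` (default) or `"lognormal"`.
#' @return Standard deviation omega of the normal random effect.
#' @export
cv_to_omega <- function(cv_percent, method = c("linear", "lognormal")) {
  method <- match.arg(method)
  stopifnot(all(cv_percent >= 0))
  if (method == "linear") cv_percent / 100
  else sqrt(log(1 + (cv_percent / 100)^2))
}

block_builders <- function() {
  list(physio = physio_constants,
       paclitaxel = paclitaxel_params,
       ritonavir = ritonavir_params,
       iv_paclitaxel = iv_paclitaxel_params,
       tsp1 = tsp1_params,
       random_effects = function(...) {
         a <- list(...)
         random_effects_spec(
           bsv_cv = unlist(a$bsv_cv),
           bov_cv = unlist(a$bov_cv),
           sigma_prop_pk = a$sigma_prop_pk %||% 25.8,
           bsv_ebase_cv = a$bsv_ebase_cv %||% 28.2,
           sigma_prop_pd = a$sigma_prop_pd %||% 13.8)
       })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a model-parameter configuration
#'
#' Reads one or more YAML files with named blocks `physio`,
#' `paclitaxel`, `ritonavir`, `iv_paclitaxel`, `tsp1` and
#' `random_effects`, validates each block through its constructor and
#' merges them (later files override earlier ones block-wise). Blocks
#' absent from every file fall back to the constructor defaults.
#'
#' @param ... Paths to YAML configuration files.
#' @return A list of class `pkpd_config` with one validated element per
#'   block.
#' @examples
#' cfg <- default_config()
#' cfg$paclitaxel$clint0
#' @export
read_config <- function(...) {
  paths <- c(...)
  raw <- list()
  for (p in paths) {
    if (!file.exists(p))
      stop("configuration file not found: ", p, call. = FALSE)
    raw <- modifyList(raw, yaml::read_yaml(p))
  }
  builders <- block_builders()
  unknown <- setdiff(names(raw), names(builders))
  if (length(unknown))
    stop("unknown configuration block(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  cfg <- lapply(names(builders), function(nm) {
    args <- raw[[nm]] %||% list()
    do.call(builders[[nm]], args)
  })
  names(cfg) <- names(builders)
  structure(cfg, class = "pkpd_config")
}

#' Default configuration (final population estimates + synthetic
#' external models)
#'
#' Convenience wrapper reading the two shipped fixtures: the oral
#' paclitaxel / TSP-1 parameter tables and the synthetic stand-in
#' values for the external ritonavir and IV paclitaxel models.
#'
#' @return A `pkpd_config` list.
#' @export
default_config <- function() {
  read_config(
    system.file("extdata", "oral_paclitaxel_params.yaml",
                package = "paxpkpd", mustWork = TRUE),
    system.file("extdata", "external_models_synthetic.yaml",
                package = "paxpkpd", mustWork = TRUE))
}

#' Write a configuration to a YAML file
#'
#' @param config A `pkpd_config` (or plain list of blocks).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  builders <- block_builders()
  blocks <- lapply(names(config), function(nm) {
    b <- unclass(config[[nm]])
    if (nm %in% names(builders) && nm != "random_effects")
      b <- b[intersect(names(b), names(formals(builders[[nm]])))]
    b <- b[!vapply(b, function(x) all(is.na(x)), logical(1))]
    # yaml drops names of atomic vectors; named lists survive as maps
    lapply(b, function(x)
      if (!is.null(names(x))) as.list(x) else x)
  })
  names(blocks) <- names(config)
  yaml::write_yaml(blocks, path)
  invisible(path)
}
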