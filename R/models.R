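#' Weibull time-varying absorption rate
#'
#' Absorption rate constant of the gut compartment,
#' `ka(t) = (beta/alpha) * (t/alpha)^(beta-1) * exp(-(t/alpha)^beta)`,
#' with `t` the time since the most recent dose. For `beta > 1` the
#' rate starts at zero, rises to a mode and decays, describing the
#' dissolution-then-absorption behaviour of the oral formulations;
#' `beta = 1` reduces to a first-order (exponential) rate.
#'
#' @param t_since_dose Time since dose (h), `>= 0`; vectorised.
#' @param alpha Weibull scale (h), `> 0`.
#' @param beta Weibull shape, `> 0`.
#' @return Rate in 1/h (the Weibull density evaluated at
#'   `t_since_dose`).
#' @examples
#' weibull_absorption_rate(1.68, alpha = 1.68, beta = 3.57)  # (3.57/1.68)/e
#' @export
weibull_absorption_rate <- function(t_since_dose, alpha, beta) {
  if (!is.finite(alpha) || alpha <= 0 || !is.finite(beta) || beta <= 0)
    stop("alpha and beta must be positive", call. = FALSE)
  if (any(t_since_dose < 0))
    stop("t_since_dose must be non-negative", call. = FALSE)
  z <- t_since_dose / alpha
  zb <- z^beta
  out <- ifelse(t_since_dose == 0,
                if (beta > 1) 0 else if (beta == 1) 1 / alpha else Inf,
                ifelse(zb > 700, 0,  # exp underflow; avoid Inf * 0
                       (beta / alpha) * z^(beta - 1) * exp(-zb)))
  as.numeric(out)
}

#' Ritonavir-inhibited intrinsic hepatic clearance
#'
#' `CLint = CLint0 - Imax * C / (KI + C)`, floored at zero: for
#' sampled individuals `clint0 * exp(eta)` can drop below the maximal
#' inhibition, and a negative clearance is unphysical. A warning is
#' emitted when flooring occurs.
#'
#' @param c_ritonavir Ritonavir plasma concentration (ng/mL), `>= 0`;
#'   vectorised.
#' @param clint0 Uninhibited intrinsic clearance (L/h).
#' @param imax Maximum inhibitory effect (L/h).
#' @param ki Ritonavir concentration of half-maximal inhibition (ng/mL).
#' @return Intrinsic clearance (L/h), monotone non-increasing in
#'   `c_ritonavir`.
#' @export
intrinsic_clearance <- function(c_ritonavir, clint0, imax, ki) {
  stopifnot(clint0 > 0, imax > 0, ki > 0)
  if (any(c_ritonavir < 0))
    stop("c_ritonavir must be non-negative", call. = FALSE)
  cl <- clint0 - imax * c_ritonavir / (ki + c_ritonavir)
  if (any(cl < 0)) {
    warning("intrinsic clearance floored at 0 (inhibition exceeds clint0)",
            call. = FALSE)
    cl <- pmax(cl, 0)
  }
  cl
}

#' Hepatic extraction ratio of the well-stirred liver model
#'
#' `E_H = CLint * fu / (Q_H + CLint * fu)`, in `[0, 1)`. The hepatic
#' bioavailability is `F_H = 1 - E_H` (see
#' [hepatic_bioavailability()]).
#'
#' @param clint Intrinsic clearance (L/h), `>= 0`; vectorised.
#' @param fu Fraction unbound, (0, 1].
#' @param qh Hepatic blood flow (L/h).
#' @return Extraction ratio.
#' @export
hepatic_extraction <- function(clint, fu, qh) {
  stopifnot(fu > 0, fu <= 1, qh > 0)
  if (any(clint < 0))
    stop("clint must be non-negative", call. = FALSE)
  clint * fu / (qh + clint * fu)
}

#' @rdname hepatic_extraction
#' @export
hepatic_bioavailability <- function(clint, fu, qh) {
  1 - hepatic_extraction(clint, fu, qh)
}

#' Inverse-Gaussian density
#'
#' Density with mean `mean` and shape `lambda`; used as the ritonavir
#' absorption input function. The relative variance of the
#' distribution is `mean/lambda`.
#'
#' @param t Time (h); vectorised; density is 0 for `t <= 0`.
#' @param mean Mean of the distribution (h), `> 0`.
#' @param lambda Shape parameter (h), `> 0`.
#' @return Density values (1/h).
#' @export
inverse_gaussian_density <- function(t, mean, lambda) {
  if (mean <= 0 || lambda <= 0)
    stop("mean and lambda must be positive", call. = FALSE)
  out <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  out[pos] <- sqrt(lambda / (2 * pi * tp^3)) *
    exp(-lambda * (tp - mean)^2 / (2 * mean^2 * tp))
  out
}

#' Ritonavir absorption input rate
#'
#' Zero-order-in-amount input `F * dose * g(t)` where `g` is an
#' inverse-Gaussian density with mean equal to the mean absorption
#' time and relative variance `input_shape`; the total amount entering
#' the central compartment is `F * dose`.
#'
#' @param t_since_dose Time since the ritonavir dose (h); vectorised.
#' @param dose Dose (mg), `> 0`.
#' @param params A [ritonavir_params()] list.
#' @return Input rate in mg/h.
#' @export
inverse_gaussian_input <- function(t_since_dose, dose, params) {
  stopifnot(inherits(params, "ritonavir_params"), dose > 0)
  lambda <- params$mean_absorption_time / params$input_shape
  params$bioavailable_fraction * dose *
    inverse_gaussian_density(t_since_dose, params$mean_absorption_time,
                             lambda)
}

#' Emax stimulation of TSP-1 formation
#'
#' Multiplier on the zero-order TSP-1 formation rate,
#' `1 + C / (EC50 + C)`, in `[1, 2)`: the implicit maximum effect is a
#' doubling of formation.
#'
#' @param c_paclitaxel Paclitaxel plasma concentration (ng/mL), `>= 0`;
#'   vectorised.
#' @param ec50 Concentration of half-maximal stimulation (ng/mL).
#' @return Dimensionless multiplier, monotone increasing in
#'   `c_paclitaxel`.
#' @export
kin_stimulation <- function(c_paclitaxel, ec50) {
  stopifnot(ec50 > 0)
  if (any(c_paclitaxel < 0))
    stop("c_paclitaxel must be non-negative", call. = FALSE)
  1 + c_paclitaxel / (ec50 + c_paclitaxel)
}

#' TSP-1 turnover derivative
#'
#' `dC/dt = kin0 * (1 + C_pac/(EC50 + C_pac)) - kout * C`. With no
#' paclitaxel and `C` at baseline the derivative is zero by the
#' steady-state construction `kin0 = baseline * kout`.
#'
#' @param c_tsp1 Current TSP-1 concentration (ng/mL per 10^6 platelets).
#' @param c_paclitaxel Paclitaxel plasma concentration (ng/mL).
#' @param params A [tsp1_params()] list.
#' @return Time derivative of the TSP-1 concentration.
#' @export
tsp1_rhs <- function(c_tsp1, c_paclitaxel, params) {
  stopifnot(inherits(params, "tsp1_params"))
  params$kin0 * kin_stimulation(c_paclitaxel, params$ec50) -
    params$kout * c_tsp1
}

#' Ritonavir two-compartment derivatives (reference implementation)
#'
#' Right-hand side of the ritonavir system: central and peripheral
#' amounts in ug, inverse-Gaussian dose input summed over all doses.
#' Concentrations follow the ug/L (= ng/mL) convention. This is the R
#' reference for the compiled solver core and is used directly in
#' tests.
#'
#' @param state Numeric length 2: central and peripheral amounts (ug).
#' @param t Time (h).
#' @param params A [ritonavir_params()] list.
#' @param doses Data frame with columns `time` (h) and `amount_mg`.
#' @return Numeric length 2 of derivatives (ug/h).
#' @export
ritonavir_rhs <- function(state, t, params, doses) {
  stopifnot(inherits(params, "ritonavir_params"), length(state) == 2)
  input <- 0
  if (!is.null(doses) && nrow(doses) > 0) {
    lambda <- params$mean_absorption_time / params$input_shape
    input <- sum(params$bioavailable_fraction * doses$amount_mg * 1000 *
                   inverse_gaussian_density(t - doses$time,
                                            params$mean_absorption_time,
                                            lambda))
  }
  cl <- params$clearance; vc <- params$vc
  q <- params$q_inter; vp <- params$vp
  c(input - (cl / vc) * state[1] - (q / vc) * state[1] + (q / vp) * state[2],
    (q / vc) * state[1] - (q / vp) * state[2])
}

#' Oral paclitaxel derivatives (reference implementation)
#'
#' Right-hand side of the gut/liver/central/peripheral system with one
#' gut compartment (and absorption clock) per dose, Weibull absorption,
#' and well-stirred-liver elimination with ritonavir-inhibited
#' intrinsic clearance. Amounts in ug; `c_ritonavir_fn` must return
#' ng/mL. The R reference for the compiled solver core.
#'
#' @param state Numeric of length `nrow(active_doses) + 3`: per-dose gut
#'   amounts, then liver, central and peripheral amounts (ug).
#' @param t Time (h).
#' @param params A [paclitaxel_params()] list (population or
#'   individual values).
#' @param physio A [physio_constants()] list.
#' @param c_ritonavir_fn Function of time returning the ritonavir
#'   plasma concentration (ng/mL).
#' @param active_doses Data frame with columns `time`, `alpha`, `beta`
#'   (absorption parameters resolved per dose) and, for
#'   `absorption = "input"`, `amount_ug`.
#' @param absorption `"hazard"` (Weibull density as time-varying rate on
#'   the gut amount, the default) or `"input"` (direct density input).
#' @return Numeric vector of derivatives matching `state`.
#' @export
oral_paclitaxel_rhs <- function(state, t, params, physio, c_ritonavir_fn,
                                active_doses,
                                absorption = c("hazard", "input")) {
  absorption <- match.arg(absorption)
  nd <- if (is.null(active_doses)) 0 else nrow(active_doses)
  stopifnot(length(state) == nd + 3)
  crtv <- c_ritonavir_fn(t)
  clint <- max(0, params$clint0 -
                 params$imax * crtv / (params$ki + crtv))
  qh <- physio$hepatic_blood_flow
  fu <- physio$fraction_unbound
  dgut <- numeric(nd)
  absin <- 0
  if (nd > 0) {
    for (d in seq_len(nd)) {
      tau <- t - active_doses$time[d]
      ka <- if (tau > 0)
        weibull_absorption_rate(tau, active_doses$alpha[d],
                                active_doses$beta[d]) else 0
      rate <- if (absorption == "input")
        active_doses$amount_ug[d] * ka else ka * state[d]
      dgut[d] <- -rate
      absin <- absin + rate
    }
  }
  ch <- state[nd + 1] / physio$liver_volume
  cc <- state[nd + 2] / params$vc
  cp <- state[nd + 3] / params$vp
  c(dgut,
    absin + qh * (cc - ch) - fu * clint * ch,
    qh * (ch - cc) - params$q * cc + params$q * cp,
    params$q * (cc - cp))
}

#' IV paclitaxel three-compartment derivatives
#'
#' Standard mamillary three-compartment model with zero-order infusion
#' input and either linear or saturable elimination from the central
#' compartment. Overlapping infusions are additive.
#'
#' @param state Numeric length 3: central and two peripheral amounts
#'   (ug).
#' @param t Time (h).
#' @param params An [iv_paclitaxel_params()] list.
#' @param infusions Data frame with columns `time` (start, h),
#'   `duration` (h) and `amount_mg`; the zero-order rate is
#'   `amount/duration`.
#' @return Numeric length 3 of derivatives (ug/h).
#' @export
iv_paclitaxel_rhs <- function(state, t, params, infusions) {
  stopifnot(inherits(params, "iv_paclitaxel_params"), length(state) == 3)
  rate <- 0
  if (!is.null(infusions) && nrow(infusions) > 0) {
    if (any(infusions$amount_mg < 0) || any(infusions$duration <= 0))
      stop("infusion amounts must be non-negative and durations positive",
           call. = FALSE)
    on <- t >= infusions$time & t < infusions$time + infusions$duration
    rate <- sum(infusions$amount_mg[on] * 1000 / infusions$duration[on])
  }
  cc <- state[1] / params$vc
  c1 <- state[2] / params$vp1
  c2 <- state[3] / params$vp2
  elim <- if (params$elimination == "linear") params$clearance * cc
  else params$vmax * cc / (params$km + cc)
  c(rate - elim - params$q1 * (cc - c1) - params$q2 * (cc - c2),
    params$q1 * (cc - c1),
    params$q2 * (cc - c2))
}
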