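# Approximate marginal-likelihood estimation for the nonlinear
# mixed-effects layer: Laplace approximation with interaction (the
# proportional-error variance follows the individual prediction), an
# outer optimization over log-transformed fixed effects and variance
# components, and sequential PK -> PD fitting with the population PK
# parameters fixed.

#' Penalized individual negative log-likelihood (-2 log joint density)
#'
#' For one subject,
#' `sum_j [log(2 pi sigma_j^2 yhat_j^2) + (y_j - yhat_j)^2 / (sigma_j^2 yhat_j^2)]
#'  + eta' Omega^-1 eta + log|2 pi Omega|`
#' under the proportional error model (the interaction: the residual
#' variance scales with the squared individual prediction); the
#' additive variant replaces `sigma_j^2 yhat_j^2` by `sigma_j^2`. A
#' non-positive prediction against a non-zero observation yields an
#' essentially infinite (very large finite) contribution.
#'
#' @param eta Random-effect vector (may be length 0 for a pooled fit).
#' @param predict_fn Function mapping `eta` to the prediction vector
#'   matching `y`.
#' @param y Observation vector.
#' @param omega Random-effect covariance matrix (positive definite),
#'   or `NULL` when `length(eta) == 0`.
#' @param sigma Residual SD, scalar or one value per observation.
#' @param error `"proportional"` or `"additive"`.
#' @return Scalar, -2 times the log of the joint density of `(y, eta)`.
#' @export
individual_penalized_nll <- function(eta, predict_fn, y, omega, sigma,
                                     error = c("proportional",
                                               "additive")) {
  error <- match.arg(error)
  yhat <- predict_fn(eta)
  if (length(yhat) != length(y))
    stop("prediction length does not match observations", call. = FALSE)
  sigma <- rep(sigma, length.out = length(y))
  v <- if (error == "proportional")
    sigma^2 * pmax(yhat, 1e-10)^2 else sigma^2
  res <- sum(log(2 * pi * v) + (y - yhat)^2 / v)
  if (length(eta)) {
    oi <- solve(omega)
    res <- res + drop(t(eta) %*% oi %*% eta) +
      length(eta) * log(2 * pi) + determinant(omega)$modulus[1]
  }
  res
}

# Central finite-difference Hessian.
fd_hessian <- function(f, x, h = NULL) {
  d <- length(x)
  h <- h %||% pmax(1e-3, 1e-3 * abs(x))
  H <- matrix(0, d, d)
  for (i in seq_len(d)) {
    ei <- replace(numeric(d), i, h[i])
    f0 <- f(x)
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i > 1) for (j in seq_len(i - 1)) {
      ej <- replace(numeric(d), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) -
           f(x - ei + ej) + f(x - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  H
}

# Forward finite-difference Jacobian of the predictions.
fd_jacobian <- function(predict_fn, eta, yhat, h = 1e-4) {
  d <- length(eta)
  J <- matrix(0, length(yhat), d)
  for (i in seq_len(d)) {
    ei <- replace(numeric(d), i, h)
    J[, i] <- (predict_fn(eta + ei) - yhat) / h
  }
  J
}

# Gauss-Newton (linearized) Hessian of the penalized -2 log-likelihood
# at etahat, the standard first-order-conditional curvature, with the
# interaction term from the prediction-dependent proportional
# variance. Positive definite by construction; exact for linear
# models with additive error.
gn_hessian <- function(J, yhat, omega_inv, sigma, error) {
  sigma <- rep(sigma, length.out = length(yhat))
  w <- if (error == "proportional") {
    yh <- pmax(yhat, 1e-10)
    1 / (sigma^2 * yh^2) + 2 / yh^2
  } else 1 / sigma^2
  2 * (crossprod(J * sqrt(w)) + omega_inv)
}

# Analytic gradient of the penalized -2 log-likelihood given the
# prediction Jacobian.
gn_gradient <- function(J, yhat, y, eta, omega_inv, sigma, error) {
  sigma <- rep(sigma, length.out = length(yhat))
  if (error == "proportional") {
    yh <- pmax(yhat, 1e-10)
    r <- y - yhat
    coef <- 2 / yh - 2 * r / (sigma^2 * yh^2) - 2 * r^2 / (sigma^2 * yh^3)
  } else {
    coef <- -2 * (y - yhat) / sigma^2
  }
  drop(crossprod(J, coef)) + 2 * drop(omega_inv %*% eta)
}

# Gauss-Newton inner minimization of the penalized -2 log-likelihood
# over eta, with step halving. Returns the optimum plus the Jacobian
# there (reused for the Laplace determinant).
gn_inner <- function(predict_fn, y, omega_inv, sigma, error, start,
                     g, max_iter = 40) {
  eta <- start
  yhat <- predict_fn(eta)
  g0 <- g(eta)
  conv <- FALSE
  J <- NULL
  for (it in seq_len(max_iter)) {
    J <- fd_jacobian(predict_fn, eta, yhat)
    grad <- gn_gradient(J, yhat, y, eta, omega_inv, sigma, error)
    H <- gn_hessian(J, yhat, omega_inv, sigma, error)
    delta <- tryCatch(-solve(H, grad), error = function(e) NULL)
    if (is.null(delta)) break
    # cap the step: protects the integrator from absurd excursions
    if (max(abs(delta)) > 3) delta <- delta * 3 / max(abs(delta))
    step <- 1
    repeat {
      eta_new <- eta + step * delta
      g_new <- g(eta_new)
      if (is.finite(g_new) && g_new <= g0 + 1e-10) break
      step <- step / 2
      if (step < 1 / 64) break
    }
    if (step < 1 / 64) { conv <- TRUE; break }  # no further descent
    moved <- max(abs(step * delta))
    improved <- g0 - g_new
    eta <- eta_new
    yhat <- predict_fn(eta)
    g0 <- g_new
    if (moved < 1e-5 || improved < 1e-8) { conv <- TRUE; break }
  }
  if (is.null(J)) J <- fd_jacobian(predict_fn, eta, yhat)
  list(eta = eta, objective = g0, yhat = yhat, J = J,
       converged = conv)
}

# Laplace -2 log marginal likelihood contribution of one subject:
# inner Gauss-Newton minimization of the penalized nll over eta
# (multi-start: previous optimum, then the origin if it did not
# converge), then g(etahat) - d log(2 pi) + log det(H/2) with H the
# linearized curvature of g at etahat ("gn"; full central
# finite differences with "fd"). Exact for linear-Gaussian subjects.
laplace_subject <- function(predict_fn, y, omega, sigma,
                            error = "proportional", warm = NULL,
                            hessian = c("gn", "fd")) {
  hessian <- match.arg(hessian)
  g <- function(e) individual_penalized_nll(e, predict_fn, y, omega,
                                            sigma, error)
  d <- if (is.null(omega)) 0L else nrow(omega)
  if (d == 0L)
    return(list(ofv = g(numeric(0)), eta = numeric(0),
                converged = TRUE))
  omega_inv <- solve(omega)
  starts <- list(numeric(d))
  if (!is.null(warm) && length(warm) == d && all(is.finite(warm)))
    starts <- c(list(warm), starts)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(gn_inner(predict_fn, y, omega_inv, sigma, error,
                             s, g),
                    error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$objective) &&
        (is.null(best) || fit$objective < best$objective)) {
      keep_going <- is.null(best) && !fit$converged
      best <- fit
      if (!keep_going) break  # converged (or no better start left)
    }
  }
  if (is.null(best) || !is.finite(best$objective))
    return(list(ofv = 1e10, eta = rep(0, d), converged = FALSE))
  H <- if (hessian == "gn")
    gn_hessian(best$J, best$yhat, omega_inv, sigma, error)
  else fd_hessian(g, best$eta)
  ld <- tryCatch({
    ch <- chol(H / 2)
    2 * sum(log(diag(ch)))
  }, error = function(e) NA_real_)
  if (is.na(ld)) {
    # ridge fallback for an indefinite finite-difference Hessian
    ridge <- 1e-8 * max(1, max(abs(diag(H))))
    ld <- determinant(H / 2 + diag(ridge, d))$modulus[1]
  }
  ofv <- best$objective - d * log(2 * pi) + ld
  # an astronomically large optimum is the signature of a predictor
  # stuck on the failure floor: never report it as converged
  list(ofv = ofv, eta = best$eta,
       converged = best$converged && ofv < 1e12)
}

#' Laplace marginal -2 log-likelihood over independent subjects
#'
#' Sums the Laplace approximation of each subject's marginal
#' likelihood. Exact for linear-Gaussian subject models. Subjects are
#' supplied generically so the routine can be checked against
#' closed-form oracles.
#'
#' @param subjects List of subjects, each a list with elements
#'   `predict_fn` (function of eta) and `y`; an optional `sigma`
#'   element overrides the shared residual SD.
#' @param omega Random-effect covariance matrix (or `NULL` for a
#'   pooled model).
#' @param sigma Residual SD (scalar or per-observation), used for
#'   subjects without their own.
#' @param error `"proportional"` or `"additive"`.
#' @param etas Optional list of warm-start etas, one per subject.
#' @return List with `ofv` (the objective function value, -2 log L),
#'   `etas` (empirical Bayes estimates) and `converged` per subject.
#' @export
laplace_marginal_nll <- function(subjects, omega, sigma,
                                 error = c("proportional", "additive"),
                                 etas = NULL) {
  error <- match.arg(error)
  out <- lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    laplace_subject(s$predict_fn, s$y, omega, s$sigma %||% sigma,
                    error, warm = etas[[i]] %||% NULL)
  })
  list(ofv = sum(vapply(out, `[[`, numeric(1), "ofv")),
       etas = lapply(out, `[[`, "eta"),
       converged = vapply(out, `[[`, logical(1), "converged"))
}

#' Likelihood-ratio comparison of nested models
#'
#' A drop in objective function value (OFV, -2 log-likelihood) between
#' nested models is significant at p < 0.01 when it exceeds the 99%
#' chi-squared quantile: 6.63 for one degree of freedom, 9.21 for two.
#'
#' @param ofv_full OFV of the richer model.
#' @param ofv_reduced OFV of the nested, reduced model.
#' @param df Difference in number of parameters.
#' @return List with `significant`, `dofv` (`ofv_reduced - ofv_full`),
#'   `threshold` and `df`. A negative `dofv` (numerical noise for truly
#'   nested fits) triggers a warning.
#' @export
lrt_compare <- function(ofv_full, ofv_reduced, df = 1) {
  stopifnot(df >= 1)
  dofv <- ofv_reduced - ofv_full
  if (dofv < 0)
    warning("negative dOFV for nested models (numerical noise?)",
            call. = FALSE)
  threshold <- qchisq(0.99, df)
  list(significant = dofv > threshold, dofv = dofv,
       threshold = threshold, df = df)
}

# Run one integrator call with a self-healing failure path: after an
# aborted run, a trivial clean solve resets the integrator before the
# same call is retried, first at the requested and then at relaxed
# tolerances. Returns NULL if everything fails.
solve_with_reset <- function(args) {
  sol <- try(suppressWarnings(do.call(deSolve::lsoda, args)),
             silent = TRUE)
  good <- function(s) !inherits(s, "try-error") &&
    attr(s, "istate")[1] >= 0 && nrow(s) == length(args$times) &&
    all(is.finite(s))
  if (good(sol)) return(sol)
  for (relax in c(1, 100)) {
    deSolve::lsoda(c(x = 1), c(0, 1),
                   function(t, y, p) list(-y), NULL)
    a <- args
    a$rtol <- max(args$rtol * relax, 1e-8 * relax)
    a$atol <- max(args$atol * relax, 1e-10 * relax)
    sol <- try(suppressWarnings(do.call(deSolve::lsoda, a)),
               silent = TRUE)
    if (good(sol)) return(sol)
  }
  NULL
}

# Wrap a raw predictor so optimizer excursions that defeat the
# integrator yield a floored (hence astronomically penalized but
# finite) prediction instead of an error.
safe_predict <- function(raw, nobs) {
  function(e) {
    v <- tryCatch(raw(e), error = function(err) NULL)
    if (is.null(v) || length(v) != nobs || !all(is.finite(v)))
      rep(1e-12, nobs)
    else v
  }
}

# Normalized TSP-1 turnover trajectory (baseline 1) under a stimulation
# series s on time grid tg: exact exponential step with trapezoidal
# treatment of s within each step.
tsp_gain <- function(tg, s, kout) {
  n <- length(tg)
  G <- numeric(n)
  G[1] <- 1
  if (n > 1) for (k in 2:n) {
    ek <- exp(-kout * (tg[k] - tg[k - 1]))
    G[k] <- G[k - 1] * ek + (1 - ek) * (s[k] + s[k - 1]) / 2
  }
  G
}

# Derivative-free outer optimization on the log scale: Nelder-Mead for
# several parameters, Brent line search for one. The marginal
# objective carries small inner-optimization noise, which
# gradient-based outer methods amplify.
outer_optimize <- function(x0, fn, maxit = 300, reltol = 1e-7) {
  if (length(x0) == 1) {
    opt <- optim(x0, fn, method = "Brent",
                 lower = x0 - log(50), upper = x0 + log(50),
                 control = list(maxit = maxit))
  } else {
    opt <- optim(x0, fn, method = "Nelder-Mead",
                 control = list(maxit = maxit, reltol = reltol))
  }
  list(par = opt$par, objective = opt$value,
       convergence = opt$convergence,
       message = opt$message %||% "",
       iterations = opt$counts[[1]])
}

# ---- PK/PD subject machinery -------------------------------------------

# Solver skeleton for one subject: solve times, output row indices,
# event template and dose covariates, so the per-evaluation work during
# estimation is pure numeric assembly plus one integrator call.
make_skeleton <- function(id, pac, rtv, t_pac, y_pac, t_tsp, y_tsp) {
  nd <- nrow(pac)
  times <- sort(unique(c(0, t_pac, t_tsp,
                         pac$time[pac$time > 0],
                         rtv$time[rtv$time > 0])))
  late <- which(pac$time > 0)
  rtv_late <- rtv$time[rtv$time > 0]
  # all-numeric event matrix (method 2 = add); gut deposits for
  # paclitaxel doses, zero-value restart markers at ritonavir doses
  ev <- NULL
  ev_dose_rows <- integer(0)
  n_ev <- length(late) + length(rtv_late)
  if (n_ev > 0) {
    ev <- cbind(var = c(late + 2L, rep(1L, length(rtv_late))),
                time = c(pac$time[late], rtv_late),
                value = 0, method = 2)
    ord <- order(ev[, "time"], ev[, "var"])
    ev <- ev[ord, , drop = FALSE]
    ev_dose_rows <- match(seq_along(late), ord)
  }
  y0 <- numeric(nd + 7L)
  names(y0) <- c("rtv_c", "rtv_p",
                 if (nd > 0) paste0("gut", seq_len(nd)),
                 "liver", "central", "peripheral", "auc", "tsp1")
  list(id = id, pac = pac, rtv = rtv,
       t_pac = t_pac, y_pac = y_pac, t_tsp = t_tsp, y_tsp = y_tsp,
       n_occ = if (nd > 0) length(unique(pac$occasion)) else 0L,
       times = times,
       row_pac = match(t_pac, times),
       row_tsp = match(t_tsp, times),
       ev = ev, ev_dose_rows = ev_dose_rows, late = late,
       y0 = y0)
}

# Split a record table into per-subject pieces. Each piece is a full
# solver skeleton; when PK observations stop before the last dose (as
# in metronomic designs with day-1 sampling plus late PD samples), a
# truncated PK-only skeleton `pk` is attached so PK-stage solves do not
# integrate past the last PK observation.
subject_pieces <- function(dataset) {
  validate_dataset(dataset)
  lapply(split(dataset, dataset$ID), function(sub) {
    pacd <- sub[sub$EVID == 1L & sub$CMT == "pac", ]
    occ_levels <- sort(unique(pacd$OCC))
    pac <- data.frame(time = pacd$TIME, amount_mg = pacd$AMT,
                      formulation = pacd$FORM, ddi = pacd$DDI,
                      occasion = match(pacd$OCC, occ_levels))
    rtvd <- sub[sub$EVID == 1L & sub$CMT == "rtv", ]
    rtv <- data.frame(time = rtvd$TIME, amount_mg = rtvd$AMT)
    obs_pac <- sub[sub$EVID == 0L & sub$CMT == "pac" & sub$MDV == 0L, ]
    obs_tsp <- sub[sub$EVID == 0L & sub$CMT == "tsp1" & sub$MDV == 0L, ]
    piece <- make_skeleton(sub$ID[1], pac, rtv,
                           obs_pac$TIME, obs_pac$DV,
                           obs_tsp$TIME, obs_tsp$DV)
    tmax_pk <- if (length(obs_pac$TIME)) max(obs_pac$TIME) else 0
    if (tmax_pk < max(piece$times)) {
      piece$pk <- make_skeleton(sub$ID[1],
                                pac[pac$time < tmax_pk, , drop = FALSE],
                                rtv[rtv$time < tmax_pk, , drop = FALSE],
                                obs_pac$TIME, obs_pac$DV,
                                numeric(0), numeric(0))
    }
    piece
  })
}

# Prediction function for one subject: given current population
# parameters and an eta vector (named components among alpha, clint0,
# vc, rf_gut, bov1..bovK, ebase), solve the coupled system at the
# observation times. Lean on purpose: no data-frame assembly per call.
subject_predict <- function(piece, config, eta, use_bov,
                            absorption = "hazard",
                            rtol = 1e-10, atol = 1e-12) {
  e <- function(nm) {
    if (is.null(eta) || !nm %in% names(eta)) return(0)
    unname(eta[[nm]])
  }
  pac <- config$paclitaxel
  physio <- config$physio
  rtv <- config$ritonavir
  tsp <- config$tsp1
  clint0_i <- pac$clint0 * exp(e("clint0"))
  vc_i <- pac$vc * exp(e("vc"))
  base_i <- tsp$baseline * exp(e("ebase"))
  kout <- tsp$kout

  d <- piece$pac
  nd <- nrow(d)
  bov_term <- 0
  if (use_bov && nd > 0) {
    bn <- paste0("bov", d$occasion)
    bov_term <- vapply(bn, function(nm)
      if (!is.null(eta) && nm %in% names(eta)) unname(eta[[nm]]) else 0,
      numeric(1))
  }
  alpha <- ifelse(d$ddi == 1L, pac$alpha_first_dose,
                  pac$alpha_second_dose) * exp(e("alpha"))
  beta <- ifelse(d$formulation == "solution", pac$beta_solution,
                 pac$beta_asd)
  rf_form <- c(solution = pac$rf_solution, tablet = pac$rf_tablet,
               capsule = pac$rf_capsule)[d$formulation]
  amt <- d$amount_mg * 1000 * unname(rf_form) *
    ifelse(d$ddi == 2L, pac$rf_second_over_first, 1) *
    exp(e("rf_gut") + bov_term)

  p <- numeric(PAX_NPARMS)
  p[1] <- nd
  p[2] <- nrow(piece$rtv)
  p[3] <- if (absorption == "input") 2 else 1
  p[4:10] <- c(rtv$clearance, rtv$vc, rtv$q_inter, rtv$vp,
               rtv$bioavailable_fraction, rtv$mean_absorption_time,
               rtv$mean_absorption_time / rtv$input_shape)
  p[11:19] <- c(physio$hepatic_blood_flow, physio$liver_volume,
                physio$fraction_unbound,
                clint0_i, pac$imax, pac$ki, vc_i, pac$q, pac$vp)
  p[20:22] <- c(base_i * kout, kout, tsp$ec50)
  if (nd > 0) {
    idx <- 25 + 4 * (seq_len(nd) - 1)
    p[idx] <- d$time; p[idx + 1] <- alpha; p[idx + 2] <- beta
    p[idx + 3] <- amt
  }
  if (nrow(piece$rtv) > 0) {
    idx <- 25 + 4 * nd + 2 * (seq_len(nrow(piece$rtv)) - 1)
    p[idx] <- piece$rtv$time
    p[idx + 1] <- piece$rtv$amount_mg * 1000
  }

  y0 <- piece$y0
  y0[length(y0)] <- base_i
  if (nd > 0 && length(piece$late) < nd) {
    early <- setdiff(seq_len(nd), piece$late)
    y0[early + 2L] <- amt[early]
  }
  args <- list(y = y0, times = piece$times, func = "oralpkpd_derivs",
               parms = p, dllname = "paxpkpd",
               initfunc = "oralpkpd_initmod",
               rtol = rtol, atol = atol, maxsteps = 50000)
  if (!is.null(piece$ev)) {
    ev <- piece$ev
    ev[piece$ev_dose_rows, "value"] <- amt[piece$late]
    args$events <- list(data = ev)
  }
  sol <- solve_with_reset(args)
  if (is.null(sol))
    stop("ODE integration failed during estimation", call. = FALSE)
  list(pac = sol[piece$row_pac, 1 + nd + 4] / vc_i,
       tsp = sol[piece$row_tsp, 1 + nd + 7])
}

# Eta layout for the PK stage. BOV on rf_gut gets one dimension per
# occasion; with a single occasion it is folded into the rf_gut BSV
# dimension (the sum of two independent normals), which is
# mathematically identical and cheaper.
pk_eta_layout <- function(spec, n_occ, cv_method = "linear") {
  om <- cv_to_omega(spec$bsv_cv, cv_method)
  om_bov <- cv_to_omega(spec$bov_cv[["rf_gut"]], cv_method)
  names <- character(0); sds <- numeric(0)
  for (nm in c("alpha", "clint0", "vc")) {
    if (om[[nm]] > 0) { names <- c(names, nm); sds <- c(sds, om[[nm]]) }
  }
  fold <- n_occ <= 1
  rf_sd <- if (fold) sqrt(om[["rf_gut"]]^2 + om_bov^2) else om[["rf_gut"]]
  if (rf_sd > 0) { names <- c(names, "rf_gut"); sds <- c(sds, rf_sd) }
  if (!fold && om_bov > 0) {
    names <- c(names, paste0("bov", seq_len(n_occ)))
    sds <- c(sds, rep(om_bov, n_occ))
  }
  list(names = names, sds = sds, use_bov = !fold && om_bov > 0)
}

#' Define an estimation problem
#'
#' Bundles a study dataset with the model configuration, the set of
#' fixed effects and variance components to estimate (everything else
#' stays fixed at its configuration value, mirroring `FIX` entries of
#' a run record), and solver/optimizer options.
#'
#' @param dataset A validated study dataset (see [read_dataset()]).
#' @param config A [default_config()]-style configuration holding the
#'   initial values.
#' @param estimate_fixed Names of [paclitaxel_params()] fixed effects
#'   to estimate (log-transformed internally), e.g.
#'   `c("clint0", "vc", "rf_capsule")`.
#' @param estimate_omega Names among `c("alpha", "clint0", "vc",
#'   "rf_gut")` whose BSV is estimated (as log-omega).
#' @param estimate_sigma Estimate the proportional PK residual SD.
#' @param absorption Weibull implementation, see [solve_pkpd()].
#' @param rtol,atol Solver tolerances used during estimation.
#' @param cv_method CV%-to-omega convention, see [cv_to_omega()].
#' @return A list of class `estimation_problem`.
#' @export
estimation_problem <- function(dataset, config,
                               estimate_fixed = c("clint0", "vc"),
                               estimate_omega = character(0),
                               estimate_sigma = FALSE,
                               absorption = "hazard",
                               rtol = 1e-8, atol = 1e-10,
                               cv_method = "linear",
                               outer_maxit = 300,
                               outer_reltol = 1e-7) {
  stopifnot(all(estimate_fixed %in% setdiff(names(config$paclitaxel),
                                            "rf_solution")),
            all(estimate_omega %in% c("alpha", "clint0", "vc",
                                      "rf_gut")))
  structure(list(dataset = dataset, config = config,
                 estimate_fixed = estimate_fixed,
                 estimate_omega = estimate_omega,
                 estimate_sigma = estimate_sigma,
                 absorption = absorption, rtol = rtol, atol = atol,
                 cv_method = cv_method,
                 outer_maxit = outer_maxit,
                 outer_reltol = outer_reltol),
            class = "estimation_problem")
}

#' Fit the population PK model by Laplace marginal likelihood
#'
#' Derivative-free outer optimization (Nelder-Mead on the log scale so
#' every parameter stays positive) of the summed per-subject Laplace
#' objective; inner per-subject optimizations are warm-started from
#' their previous optimum. Deterministic given the data and initial
#' values.
#'
#' @param problem An [estimation_problem()].
#' @param trace Print outer-iteration progress.
#' @return An object of class `estimation_result`: `estimates` (named,
#'   natural scale; omegas reported as CV%), `pac_params` (full
#'   updated parameter list), `re_spec` (updated variance components),
#'   `ofv`, `etas` (matrix of empirical Bayes estimates), `shrinkage`
#'   (percent, per eta dimension), `convergence` (outer optimizer code,
#'   0 = success), `flagged_subjects` (inner non-convergence at the
#'   optimum, making the OFV unreliable if non-empty).
#' @export
fit_population <- function(problem, trace = FALSE) {
  stopifnot(inherits(problem, "estimation_problem"))
  cfg <- problem$config
  pieces <- subject_pieces(problem$dataset)
  n_occ_max <- max(vapply(pieces, `[[`, numeric(1), "n_occ"))

  th_names <- problem$estimate_fixed
  om_names <- problem$estimate_omega
  x0 <- c(if (length(th_names)) log(unlist(cfg$paclitaxel[th_names])),
          if (length(om_names))
            log(cv_to_omega(cfg$random_effects$bsv_cv[om_names],
                            problem$cv_method)),
          if (problem$estimate_sigma)
            log(cfg$random_effects$sigma_prop_pk / 100))
  if (is.null(x0)) x0 <- numeric(0)
  npar <- length(x0)

  env <- new.env()
  env$etas <- vector("list", length(pieces))

  assemble <- function(x) {
    pac <- cfg$paclitaxel
    if (length(th_names))
      pac[th_names] <- as.list(exp(x[seq_along(th_names)]))
    spec <- cfg$random_effects
    if (length(om_names))
      spec$bsv_cv[om_names] <-
        100 * exp(x[length(th_names) + seq_along(om_names)])
    sigma <- if (problem$estimate_sigma) exp(x[npar])
    else cfg$random_effects$sigma_prop_pk / 100
    list(pac = pac, spec = spec, sigma = sigma)
  }

  objective <- function(x) {
    a <- assemble(x)
    cfg_x <- cfg
    cfg_x$paclitaxel <- a$pac
    total <- 0
    for (i in seq_along(pieces)) {
      p <- pieces[[i]]$pk %||% pieces[[i]]
      lay <- pk_eta_layout(a$spec, p$n_occ, problem$cv_method)
      omega <- if (length(lay$names))
        diag(lay$sds^2, length(lay$sds)) else NULL
      pf <- safe_predict(function(e) {
        names(e) <- lay$names
        subject_predict(p, cfg_x, e, lay$use_bov, problem$absorption,
                        problem$rtol, problem$atol)$pac
      }, length(p$y_pac))
      fit <- laplace_subject(pf, p$y_pac, omega, a$sigma,
                             "proportional", warm = env$etas[[i]])
      env$etas[[i]] <- fit$eta
      total <- total + fit$ofv
    }
    if (trace) message(sprintf("OFV %.4f @ %s", total,
                               paste(signif(exp(x), 5),
                                     collapse = " ")))
    if (!is.finite(total)) 1e10 else total
  }

  opt <- if (npar == 0) {
    # nothing to estimate: a single pass computing the OFV and the
    # empirical Bayes etas at the supplied values
    list(par = x0, objective = objective(x0), convergence = 0L,
         message = "no parameters estimated", iterations = 1L)
  } else {
    outer_optimize(x0, objective, problem$outer_maxit,
                   problem$outer_reltol)
  }

  # final pass at the optimum: empirical Bayes etas and diagnostics
  a <- assemble(opt$par)
  cfg_fin <- cfg; cfg_fin$paclitaxel <- a$pac
  etas <- list(); flagged <- character(0)
  lay_ref <- pk_eta_layout(a$spec, 1, problem$cv_method)
  for (i in seq_along(pieces)) {
    p <- pieces[[i]]$pk %||% pieces[[i]]
    lay <- pk_eta_layout(a$spec, p$n_occ, problem$cv_method)
    omega <- if (length(lay$names))
      diag(lay$sds^2, length(lay$sds)) else NULL
    pf <- safe_predict(function(e) {
      names(e) <- lay$names
      subject_predict(p, cfg_fin, e, lay$use_bov, problem$absorption,
                      problem$rtol, problem$atol)$pac
    }, length(p$y_pac))
    fit <- laplace_subject(pf, p$y_pac, omega, a$sigma, "proportional",
                           warm = env$etas[[i]])
    if (!fit$converged) flagged <- c(flagged, as.character(p$id))
    e <- setNames(fit$eta, lay$names)
    etas[[i]] <- e
  }
  ids <- vapply(pieces, function(p) as.character(p$id), character(1))
  base_names <- lay_ref$names
  eta_mat <- t(vapply(etas, function(e)
    vapply(base_names, function(nm)
      if (nm %in% names(e)) e[[nm]] else NA_real_, numeric(1)),
    numeric(length(base_names))))
  if (length(base_names) == 1) eta_mat <- matrix(eta_mat, ncol = 1)
  dimnames(eta_mat) <- list(ids, base_names)

  shrink <- 100 * (1 - apply(eta_mat, 2, sd, na.rm = TRUE) /
                     lay_ref$sds)
  est <- c(if (length(th_names))
             setNames(unlist(a$pac[th_names]), th_names),
           if (length(om_names))
             setNames(a$spec$bsv_cv[om_names],
                      paste0("bsv_", om_names)),
           if (problem$estimate_sigma)
             c(sigma_prop_pk = 100 * a$sigma))

  structure(list(estimates = est, pac_params = a$pac,
                 re_spec = a$spec, sigma_pk = a$sigma,
                 ofv = opt$objective, etas = eta_mat,
                 shrinkage = shrink,
                 convergence = opt$convergence,
                 message = opt$message,
                 iterations = opt$iterations,
                 flagged_subjects = flagged,
                 problem = problem),
            class = "estimation_result")
}

#' @export
print.estimation_result <- function(x, ...) {
  cat("Population estimation result\n")
  cat(sprintf("  OFV: %.3f (outer convergence code %d)\n", x$ofv,
              x$convergence))
  cat("  Estimates:\n")
  for (nm in names(x$estimates))
    cat(sprintf("    %-16s %g\n", nm, x$estimates[[nm]]))
  if (length(x$flagged_subjects))
    cat("  Flagged subjects (inner non-convergence):",
        paste(x$flagged_subjects, collapse = ", "), "\n")
  invisible(x)
}

#' Sequential PD fit with population PK parameters fixed
#'
#' Fits the TSP-1 turnover parameters with the population PK fixed
#' effects and variance components frozen at the PK-stage result. Two
#' variants of the sequential approach are available: `"joint"`
#' re-estimates each subject's PK random effects together with the
#' TSP-1 baseline effect using both PK and PD records (between-occasion
#' effects are held at zero in this stage); `"ebe"` freezes the PK
#' random effects at their PK-stage empirical Bayes estimates and fits
#' the PD records only, which is considerably faster. The turnover
#' time stays fixed (233 h by default).
#'
#' @param pk_result The PK-stage [fit_population()] result.
#' @param dataset Record table containing PD (`tsp1`) and PK rows.
#' @param estimate Names among `c("ec50", "e_base")` to estimate.
#' @param estimate_omega_ebase Estimate the BSV of the TSP-1 baseline.
#' @param estimate_sigma_pd Estimate the PD proportional residual SD.
#' @param ppp_mode `"joint"` or `"ebe"` (see above).
#' @param trace Print outer-iteration progress.
#' @return An `estimation_result` with PD estimates and OFV. With no
#'   PD records in `dataset` the PK result is returned unchanged with
#'   a warning.
#' @export
fit_pd_sequential <- function(pk_result, dataset,
                              estimate = c("ec50", "e_base"),
                              estimate_omega_ebase = FALSE,
                              estimate_sigma_pd = FALSE,
                              ppp_mode = c("joint", "ebe"),
                              trace = FALSE) {
  stopifnot(inherits(pk_result, "estimation_result"))
  ppp_mode <- match.arg(ppp_mode)
  estimate <- match.arg(estimate, c("ec50", "e_base"),
                        several.ok = TRUE)
  problem <- pk_result$problem
  cfg <- problem$config
  cfg$paclitaxel <- pk_result$pac_params
  spec <- pk_result$re_spec
  if (!any(dataset$EVID == 0L & dataset$CMT == "tsp1" &
             dataset$MDV == 0L)) {
    warning("no PD observations in dataset; returning the PK result",
            call. = FALSE)
    return(pk_result)
  }
  pieces <- subject_pieces(dataset)
  cvm <- problem$cv_method
  om_ebase0 <- cv_to_omega(spec$bsv_ebase_cv, cvm)
  sigma_pd0 <- spec$sigma_prop_pd / 100
  sigma_pk <- pk_result$sigma_pk

  map <- c(ec50 = "ec50", e_base = "baseline")
  x0 <- c(log(unlist(cfg$tsp1[map[estimate]])),
          if (estimate_omega_ebase) log(om_ebase0),
          if (estimate_sigma_pd) log(sigma_pd0))
  nth <- length(estimate)

  assemble <- function(x) {
    tsp <- tsp1_params(
      ec50 = if ("ec50" %in% estimate)
        exp(x[match("ec50", estimate)]) else cfg$tsp1$ec50,
      baseline = if ("e_base" %in% estimate)
        exp(x[match("e_base", estimate)]) else cfg$tsp1$baseline,
      turnover_time = cfg$tsp1$turnover_time)
    k <- nth
    om_eb <- if (estimate_omega_ebase) exp(x[k <- k + 1]) else om_ebase0
    sg_pd <- if (estimate_sigma_pd) exp(x[k + 1]) else sigma_pd0
    list(tsp = tsp, om_eb = om_eb, sg_pd = sg_pd)
  }

  env <- new.env(); env$etas <- vector("list", length(pieces))
  ids <- vapply(pieces, function(p) as.character(p$id), character(1))

  # With the PK random effects frozen ("ebe"), the paclitaxel driver is
  # fixed: solve it once per subject on a fine grid. The TSP-1 state is
  # then a linear turnover driven by the stimulation function, and the
  # individual baseline scales the whole trajectory, so per-evaluation
  # work reduces to an exponential-integrator pass over the grid.
  drivers <- vector("list", length(pieces))
  if (ppp_mode == "ebe") {
    for (i in seq_along(pieces)) {
      p <- pieces[[i]]
      if (!length(p$y_tsp)) next
      eta_pk <- pk_result$etas[ids[i], ]
      eta_pk <- eta_pk[!is.na(eta_pk)]
      ind2 <- apply_individual(cfg$paclitaxel, cfg$tsp1,
                               structure(list(eta = eta_pk),
                                         class = "individual_params"))
      doses <- resolve_pac_doses(p$pac, ind2$pac, eta = eta_pk,
                                 bov = NULL)
      tg <- sort(unique(c(seq(0, max(p$t_tsp), by = 0.25), p$t_tsp)))
      prof <- solve_pkpd(doses, p$rtv, ind2$pac, cfg$physio,
                         cfg$ritonavir, ind2$tsp, times = tg,
                         absorption = problem$absorption,
                         rtol = problem$rtol, atol = problem$atol)
      drivers[[i]] <- list(tg = prof$time, cpac = prof$conc_pac,
                           rows = match(p$t_tsp, prof$time))
    }
  }

  subject_fit <- function(i, a, cfg_x) {
    p <- pieces[[i]]
    has_pd <- length(p$y_tsp) > 0
    if (ppp_mode == "ebe") {
      if (!has_pd) return(list(ofv = 0, eta = numeric(0),
                               converged = TRUE))
      dr <- drivers[[i]]
      s <- kin_stimulation(pmax(dr$cpac, 0), a$tsp$ec50)
      G <- tsp_gain(dr$tg, s, a$tsp$kout)[dr$rows]
      omega <- if (a$om_eb > 0) matrix(a$om_eb^2, 1, 1) else NULL
      pf <- function(e)
        a$tsp$baseline * exp(if (length(e)) e[[1]] else 0) * G
      fit <- laplace_subject(pf, p$y_tsp, omega, a$sg_pd,
                             "proportional", warm = env$etas[[i]])
    } else {
      lay <- pk_eta_layout(spec, 1, cvm)  # BOV held at zero
      nms <- lay$names; sds <- lay$sds
      if (has_pd && a$om_eb > 0) {
        nms <- c(nms, "ebase"); sds <- c(sds, a$om_eb)
      }
      omega <- if (length(nms)) diag(sds^2, length(sds)) else NULL
      y <- c(p$y_pac, if (has_pd) p$y_tsp)
      sg <- c(rep(sigma_pk, length(p$y_pac)),
              if (has_pd) rep(a$sg_pd, length(p$y_tsp)))
      pf <- safe_predict(function(e) {
        names(e) <- nms
        pr <- subject_predict(p, cfg_x, e, use_bov = FALSE,
                              problem$absorption, problem$rtol,
                              problem$atol)
        c(pr$pac, if (has_pd) pr$tsp)
      }, length(y))
      fit <- laplace_subject(pf, y, omega, sg, "proportional",
                             warm = env$etas[[i]])
    }
    env$etas[[i]] <- fit$eta
    fit
  }

  objective <- function(x) {
    a <- assemble(x)
    cfg_x <- cfg; cfg_x$tsp1 <- a$tsp
    total <- 0
    for (i in seq_along(pieces)) {
      fit <- tryCatch(subject_fit(i, a, cfg_x),
                      error = function(e) list(ofv = 1e10))
      total <- total + fit$ofv
    }
    if (trace) message(sprintf("PD OFV %.4f @ %s", total,
                               paste(signif(exp(x), 5),
                                     collapse = " ")))
    if (!is.finite(total)) 1e10 else total
  }

  opt <- outer_optimize(x0, objective, problem$outer_maxit %||% 300,
                        problem$outer_reltol %||% 1e-7)
  a <- assemble(opt$par)
  cfg_fin <- cfg; cfg_fin$tsp1 <- a$tsp
  flagged <- character(0)
  for (i in seq_along(pieces)) {
    fit <- subject_fit(i, a, cfg_fin)
    if (!fit$converged) flagged <- c(flagged, ids[i])
  }
  est <- c(setNames(c(a$tsp$ec50, a$tsp$baseline)[
    match(estimate, c("ec50", "e_base"))], estimate),
    if (estimate_omega_ebase) c(bsv_ebase = 100 * a$om_eb),
    if (estimate_sigma_pd) c(sigma_prop_pd = 100 * a$sg_pd))

  structure(list(estimates = est, tsp_params = a$tsp,
                 pac_params = cfg$paclitaxel, re_spec = spec,
                 sigma_pk = sigma_pk, sigma_pd = a$sg_pd,
                 ofv = opt$objective,
                 etas = env$etas, shrinkage = NULL,
                 convergence = opt$convergence,
                 message = opt$message,
                 iterations = opt$iterations,
                 flagged_subjects = flagged,
                 ppp_mode = ppp_mode, problem = problem),
            class = "estimation_result")
}
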