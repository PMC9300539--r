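# Low-level interface to the compiled ritonavir/paclitaxel/TSP-1 ODE
# core. Amounts ug, volumes L, concentrations ug/L (== ng/mL), time h.

PAX_NPARMS <- 4096L

# pac_doses: data.frame(time, alpha, beta, amount_ug) with absorption
# parameters and bioavailability already resolved per dose.
# rtv_doses: data.frame(time, amount_mg) or NULL.
build_parms <- function(pac_doses, rtv_doses, pac, physio, rtv, tsp,
                        absorption) {
  nd <- if (is.null(pac_doses)) 0L else nrow(pac_doses)
  nr <- if (is.null(rtv_doses)) 0L else nrow(rtv_doses)
  if (24 + 4 * nd + 2 * nr > PAX_NPARMS)
    stop("too many dose events for the solver parameter block",
         call. = FALSE)
  p <- numeric(PAX_NPARMS)
  p[1] <- nd
  p[2] <- nr
  p[3] <- if (absorption == "input") 2 else 1
  lambda <- rtv$mean_absorption_time / rtv$input_shape
  p[4:10] <- c(rtv$clearance, rtv$vc, rtv$q_inter, rtv$vp,
               rtv$bioavailable_fraction, rtv$mean_absorption_time,
               lambda)
  p[11:19] <- c(physio$hepatic_blood_flow, physio$liver_volume,
                physio$fraction_unbound,
                pac$clint0, pac$imax, pac$ki, pac$vc, pac$q, pac$vp)
  p[20:22] <- c(tsp$kin0, tsp$kout, tsp$ec50)
  if (nd > 0) {
    idx <- 25 + 4 * (seq_len(nd) - 1)
    p[idx] <- pac_doses$time
    p[idx + 1] <- pac_doses$alpha
    p[idx + 2] <- pac_doses$beta
    p[idx + 3] <- pac_doses$amount_ug
  }
  if (nr > 0) {
    idx <- 25 + 4 * nd + 2 * (seq_len(nr) - 1)
    p[idx] <- rtv_doses$time
    p[idx + 1] <- rtv_doses$amount_mg * 1000
  }
  p
}

#' Solve the coupled ritonavir / oral paclitaxel / TSP-1 system
#'
#' Integrates the full semi-physiological system: ritonavir
#' two-compartment PK with inverse-Gaussian input, oral paclitaxel with
#' one Weibull-absorption gut compartment per dose (each with its own
#' clock), a well-stirred liver with ritonavir-inhibited intrinsic
#' clearance, linear central/peripheral disposition, a cumulative-AUC
#' accumulator and the TSP-1 turnover state. Dose times are mandatory
#' solver breakpoints (deposited through solver events).
#'
#' @param pac_doses Data frame of paclitaxel doses with columns `time`
#'   (h), `alpha`, `beta` (Weibull parameters resolved per dose) and
#'   `amount_ug` (ug entering the gut, i.e. dose x relative gut
#'   bioavailability). May be `NULL` or empty.
#' @param rtv_doses Data frame of ritonavir doses with columns `time`
#'   and `amount_mg`, or `NULL`.
#' @param pac,physio,rtv,tsp Parameter lists (individual or population
#'   values): [paclitaxel_params()], [physio_constants()],
#'   [ritonavir_params()], [tsp1_params()].
#' @param times Output time grid (h), starting at 0.
#' @param absorption `"hazard"` or `"input"`, see
#'   [oral_paclitaxel_rhs()].
#' @param tsp1_init Initial TSP-1 concentration; defaults to the
#'   baseline in `tsp`.
#' @param rtol,atol Solver tolerances (relative on all states, absolute
#'   on amounts).
#' @return A data frame with columns `time`, `conc_pac`, `conc_rtv`,
#'   `tsp1`, `auc_pac` (cumulative, ug.h/L) and the compartment amounts
#'   `amt_gut` (total), `amt_liver`, `amt_central`, `amt_peripheral`,
#'   `amt_rtv` (central + peripheral).
#' @export
solve_pkpd <- function(pac_doses, rtv_doses, pac, physio, rtv, tsp,
                       times, absorption = c("hazard", "input"),
                       tsp1_init = NULL, rtol = 1e-8, atol = 1e-10) {
  absorption <- match.arg(absorption)
  if (is.null(pac_doses) || !nrow(pac_doses))
    pac_doses <- data.frame(time = numeric(0), alpha = numeric(0),
                            beta = numeric(0), amount_ug = numeric(0))
  if (is.null(rtv_doses) || !nrow(rtv_doses))
    rtv_doses <- data.frame(time = numeric(0), amount_mg = numeric(0))
  # doses beyond the output window cannot influence it
  pac_doses <- pac_doses[pac_doses$time <= max(times), , drop = FALSE]
  rtv_doses <- rtv_doses[rtv_doses$time <= max(times), , drop = FALSE]
  nd <- nrow(pac_doses)
  parms <- build_parms(pac_doses, rtv_doses, pac, physio, rtv, tsp,
                       absorption)
  t0 <- min(0, times)
  y0 <- numeric(nd + 7L)
  names(y0) <- c("rtv_c", "rtv_p",
                 if (nd > 0) paste0("gut", seq_len(nd)),
                 "liver", "central", "peripheral", "auc", "tsp1")
  y0[nd + 7L] <- tsp1_init %||% tsp$baseline

  ev <- NULL
  if (nd > 0) {
    late <- pac_doses$time > t0
    y0[which(!late) + 2L] <- pac_doses$amount_ug[!late]
    if (any(late))
      ev <- cbind(var = which(late) + 2L,
                  time = pac_doses$time[late],
                  value = pac_doses$amount_ug[late],
                  method = 2)
  }
  # zero-value events force solver restarts at ritonavir dose times
  if (nrow(rtv_doses) > 0 && any(rtv_doses$time > t0)) {
    rt <- rtv_doses$time[rtv_doses$time > t0]
    ev <- rbind(ev, cbind(var = 1L, time = rt, value = 0, method = 2))
  }

  solve_times <- sort(unique(c(t0, times,
                               if (!is.null(ev)) ev[, "time"])))
  args <- list(y = y0, times = solve_times, func = "oralpkpd_derivs",
               parms = parms, dllname = "paxpkpd",
               initfunc = "oralpkpd_initmod",
               rtol = rtol, atol = atol, maxsteps = 50000)
  if (!is.null(ev)) {
    ev <- ev[order(ev[, "time"], ev[, "var"]), , drop = FALSE]
    args$events <- list(data = ev)
  }
  sol <- solve_with_reset(args)
  if (is.null(sol))
    stop("ODE integration failed", call. = FALSE)
  sol <- sol[sol[, 1] %in% times, , drop = FALSE]
  gut <- if (nd > 0) rowSums(sol[, 1 + 2 + seq_len(nd), drop = FALSE])
  else numeric(nrow(sol))
  data.frame(time = sol[, 1],
             conc_pac = sol[, 1 + nd + 4] / pac$vc,
             conc_rtv = sol[, 2] / rtv$vc,
             tsp1 = sol[, 1 + nd + 7],
             auc_pac = sol[, 1 + nd + 6],
             amt_gut = gut,
             amt_liver = sol[, 1 + nd + 3],
             amt_central = sol[, 1 + nd + 4],
             amt_peripheral = sol[, 1 + nd + 5],
             amt_rtv = sol[, 2] + sol[, 3])
}

#' Simulate an IV paclitaxel infusion schedule
#'
#' Solves the three-compartment IV plug-in model ([iv_paclitaxel_rhs()])
#' for a schedule of zero-order infusions; infusion start and stop
#' times are solver breakpoints.
#'
#' @param infusions Data frame with columns `time`, `duration` (h) and
#'   `amount_mg`.
#' @param params An [iv_paclitaxel_params()] list.
#' @param times Output time grid (h).
#' @param rtol,atol Solver tolerances.
#' @return Data frame with `time`, `conc_pac` (ng/mL) and `auc_pac`
#'   (cumulative, ug.h/L).
#' @export
simulate_iv <- function(infusions, params, times, rtol = 1e-8,
                        atol = 1e-10) {
  stopifnot(inherits(params, "iv_paclitaxel_params"))
  rhs <- function(t, y, p) {
    d <- iv_paclitaxel_rhs(y[1:3], t, params, infusions)
    list(c(d, y[1] / params$vc))
  }
  brk <- c(infusions$time, infusions$time + infusions$duration)
  solve_times <- sort(unique(c(times, brk[brk >= min(times) &
                                            brk <= max(times)])))
  sol <- deSolve::lsoda(c(0, 0, 0, 0), solve_times, rhs, NULL,
                        rtol = rtol, atol = atol, maxsteps = 50000)
  if (attr(sol, "istate")[1] < 0)
    stop("IV ODE integration failed", call. = FALSE)
  sol <- sol[sol[, 1] %in% times, , drop = FALSE]
  data.frame(time = sol[, 1], conc_pac = sol[, 2] / params$vc,
             auc_pac = sol[, 5])
}
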