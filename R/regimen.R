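#' Build a dosing regimen from a design description
#'
#' Expands a compact design description into explicit dose events for
#' one subject: paclitaxel doses with formulation, daily-dose index and
#' sequential occasion numbers, and the accompanying ritonavir doses.
#' Twice-daily designs place the second dose `interval_h` (default 7 h)
#' after the first; ritonavir can lead paclitaxel (e.g. the 30-min
#' pre-dose administration of the drinking-solution studies), in which
#' case time zero is the first ritonavir administration so that all
#' times stay non-negative.
#'
#' Design fields (all optional unless noted): `pac_dose_mg` (per
#' administration; scalar or one value per dose), `formulation`
#' (`"solution"`, `"capsule"`, `"tablet"`), `n_days`, `doses_per_day`
#' (1 or 2), `interval_h`, `rtv_dose_mg` (per administration, scalar;
#' `NULL` for none), `rtv_lead_h` (how long ritonavir precedes each
#' paclitaxel dose), `rtv_doses_per_day`, and `grid` (observation time
#' grid in h, relative to the first paclitaxel dose).
#'
#' @param design A named list as described above. An empty list yields
#'   an empty, valid regimen.
#' @return An object of class `regimen`: list with data frames `pac`
#'   (`time`, `amount_mg`, `formulation`, `ddi`, `occasion`), `rtv`
#'   (`time`, `amount_mg`) and the numeric `grid`.
#' @examples
#' reg <- build_regimen(rp2d_design(n_days = 1))
#' reg$pac
#' @export
build_regimen <- function(design = list()) {
  stopifnot(is.list(design))
  known <- c("pac_dose_mg", "formulation", "n_days", "doses_per_day",
             "interval_h", "rtv_dose_mg", "rtv_lead_h",
             "rtv_doses_per_day", "grid", "pac_times", "rtv_times")
  unknown <- setdiff(names(design), known)
  if (length(unknown))
    stop("unknown design field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(design$pac_dose_mg)) {
    return(structure(list(
      pac = data.frame(time = numeric(0), amount_mg = numeric(0),
                       formulation = character(0), ddi = integer(0),
                       occasion = integer(0)),
      rtv = data.frame(time = numeric(0), amount_mg = numeric(0)),
      grid = design$grid %||% numeric(0)), class = "regimen"))
  }
  form <- design$formulation %||% "tablet"
  if (!all(form %in% c("solution", "capsule", "tablet")))
    stop("unknown formulation code", call. = FALSE)
  n_days <- design$n_days %||% 1L
  dpd <- design$doses_per_day %||% 1L
  stopifnot(n_days >= 1, dpd %in% c(1L, 2L))
  interval <- design$interval_h %||% 7
  lead <- design$rtv_lead_h %||% 0
  offset <- if (lead > 0) lead else 0

  if (!is.null(design$pac_times)) {
    pt <- design$pac_times + offset
  } else {
    pt <- offset + rep((seq_len(n_days) - 1) * 24, each = dpd) +
      rep(if (dpd == 2) c(0, interval) else 0, times = n_days)
  }
  if (anyDuplicated(pt))
    stop("overlapping identical paclitaxel dose times", call. = FALSE)
  amt <- design$pac_dose_mg
  if (length(amt) == 1) amt <- rep(amt, length(pt))
  if (length(amt) != length(pt))
    stop("pac_dose_mg must be scalar or one value per dose",
         call. = FALSE)
  if (any(amt <= 0)) stop("dose amounts must be positive", call. = FALSE)
  pac <- data.frame(time = pt, amount_mg = amt,
                    formulation = rep(form, length.out = length(pt)),
                    ddi = assign_daily_dose_index(pt),
                    occasion = seq_along(pt))

  rtv <- data.frame(time = numeric(0), amount_mg = numeric(0))
  if (!is.null(design$rtv_dose_mg)) {
    if (!is.null(design$rtv_times)) {
      rt <- design$rtv_times + offset
    } else {
      rdpd <- design$rtv_doses_per_day %||% dpd
      rt <- offset - lead + rep((seq_len(n_days) - 1) * 24, each = rdpd) +
        rep(if (rdpd == 2) c(0, interval) else 0, times = n_days)
    }
    rtv <- data.frame(time = rt,
                      amount_mg = rep(design$rtv_dose_mg,
                                      length.out = length(rt)))
  }
  grid <- design$grid %||% (offset + seq(0, 24, by = 0.25))
  structure(list(pac = pac, rtv = rtv, grid = sort(unique(grid))),
            class = "regimen")
}

#' Daily-dose index of oral dose times
#'
#' Index 1 for the first dose within each 24-h block counted from the
#' first dose, 2 for any later dose in the same block. The first daily
#' dose uses the first-dose Weibull scale and full relative
#' bioavailability; the second uses the second-dose scale and the
#' additional second-versus-first bioavailability factor.
#'
#' @param times Dose times (h).
#' @return Integer vector of the same length.
#' @export
assign_daily_dose_index <- function(times) {
  if (!length(times)) return(integer(0))
  ord <- order(times)
  day <- floor((times[ord] - times[ord][1]) / 24)
  idx <- stats::ave(day, day, FUN = seq_along)
  out <- integer(length(times))
  out[ord] <- pmin(idx, 2L)
  out
}

#' Design for the recommended phase II tablet regimen
#'
#' 20 mg paclitaxel tablet twice daily with a 7-h interval,
#' co-administered with 100 mg ritonavir twice daily, for `n_days`
#' days (3 weeks by default).
#'
#' @param n_days Number of dosing days.
#' @param formulation `"tablet"` (default) or `"capsule"` for the
#'   formulation-comparison simulations at the same dose level.
#' @param grid Observation grid (h); default covers the full dosing
#'   period plus 24 h at 0.25-h resolution.
#' @return A design list for [build_regimen()].
#' @export
rp2d_design <- function(n_days = 21, formulation = "tablet",
                        grid = NULL) {
  list(pac_dose_mg = 20, formulation = formulation, n_days = n_days,
       doses_per_day = 2L, interval_h = 7, rtv_dose_mg = 100,
       rtv_lead_h = 0, rtv_doses_per_day = 2L,
       grid = grid %||% seq(0, n_days * 24, by = 0.05))
}
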