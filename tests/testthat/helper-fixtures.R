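# Shared fixtures: the shipped configuration (population estimates plus
# the synthetic stand-ins for the external ritonavir / IV models) and a
# few small designs reused across tests.

pax_cfg <- default_config()

# single-dose design mixing the drinking solution (100 mg, as in the
# proof-of-concept study) and the capsule (30 mg), ritonavir 30 min
# before paclitaxel
mixed_single_dose_spec <- function(n = 10) {
  trial_design_spec("custom", n_subjects = n,
                    daily_dose_mg = rep(c(100, 30), each = ceiling(n / 2))[1:n],
                    formulation = rep(c("solution", "capsule"),
                                      each = ceiling(n / 2))[1:n],
                    rtv_dose_mg = 100, rtv_lead_h = 0.5)
}

# a no-variability truth: every subject is the typical one
zero_re_config <- function(cfg = pax_cfg, sigma_pk = 0, sigma_pd = 0) {
  cfg$random_effects <- random_effects_spec(
    bsv_cv = c(alpha = 0, clint0 = 0, vc = 0, rf_gut = 0),
    bov_cv = c(rf_gut = 0),
    sigma_prop_pk = sigma_pk, bsv_ebase_cv = 0,
    sigma_prop_pd = sigma_pd)
  cfg
}

single_dose_regimen <- function(dose_mg = 100, formulation = "solution",
                                by = 0.05) {
  build_regimen(list(pac_dose_mg = dose_mg, formulation = formulation,
                     rtv_dose_mg = 100, rtv_lead_h = 0.5,
                     grid = 0.5 + seq(0, 24, by = by)))
}
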