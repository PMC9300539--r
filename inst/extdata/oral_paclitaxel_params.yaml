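# Final population parameter estimates of the oral paclitaxel PK model
# and the TSP-1 turnover PD model, plus the fixed physiological
# constants of the well-stirred liver model.
physio:
  hepatic_blood_flow: 80      # L/h, fixed
  liver_volume: 1             # L, fixed
  fraction_unbound: 0.13      # fixed literature value
paclitaxel:
  alpha_first_dose: 1.68      # Weibull scale, first daily dose (h)
  alpha_second_dose: 1.97     # Weibull scale, second daily dose (h)
  beta_solution: 2.53         # Weibull shape, drinking solution
  beta_asd: 3.57              # Weibull shape, tablet + capsule
  clint0: 746                 # uninhibited intrinsic clearance (L/h)
  ki: 375                     # ritonavir half-maximal conc (ng/mL)
  imax: 570                   # maximal inhibitory effect (L/h)
  vc: 128                     # central volume (L)
  q: 33.4                     # inter-compartmental clearance (L/h)
  vp: 375                     # peripheral volume (L)
  rf_solution: 1              # relative gut bioavailability, FIX
  rf_tablet: 0.97
  rf_capsule: 0.46
  rf_second_over_first: 0.59
tsp1:
  ec50: 284                   # ng/mL
  baseline: 43.8              # ng/mL per 1e6 platelets
  turnover_time: 233          # h, FIX (platelet survival)
random_effects:
  bsv_cv:                     # between-subject variability, CV%
    alpha: 35.1
    clint0: 25.1
    vc: 53.8
    rf_gut: 38.2
  bov_cv:                     # between-occasion variability, CV%
    rf_gut: 45.8
  sigma_prop_pk: 25.8         # proportional residual error PK, CV%
  bsv_ebase_cv: 28.2          # BSV of the TSP-1 baseline, CV%
  sigma_prop_pd: 13.8         # proportional residual error PD, CV%
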