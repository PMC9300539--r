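---
title: "Population PK/PD of oral paclitaxel boosted with ritonavir"
author: "paxpkpd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population PK/PD of oral paclitaxel boosted with ritonavir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Paclitaxel is poorly bioavailable orally: it dissolves badly, is pumped
back into the gut lumen by P-glycoprotein, and undergoes extensive
first-pass metabolism by CYP3A4 (and CYP2C8). Two strategies together
make low-dose metronomic (LDM) oral dosing feasible: amorphous
solid-dispersion (ASD) formulations (capsule and tablet) that address
dissolution, and co-administration of ritonavir, a strong CYP3A4
inhibitor, which suppresses first-pass extraction. `paxpkpd` implements
a semi-physiological population model of this system, a turnover model
linking paclitaxel exposure to the anti-angiogenic platelet protein
thrombospondin-1 (TSP-1), the mixed-effects statistical machinery to
estimate the model from longitudinal concentration records, and a
synthetic-trial generator that emulates the three early-phase study
designs the model was developed on, so that the entire analysis is
testable without patient data.

## Structural model

**Ritonavir** follows a two-compartment model with first-order
elimination and an inverse-Gaussian density absorption input
(`inverse_gaussian_input()`): the input rate is `F * dose * g(t)` with
`g` an inverse-Gaussian density parameterised by its mean (the mean
absorption time) and a relative-variance shape parameter. The
published parameter values of this model are not part of the package;
the shipped `external_models_synthetic.yaml` carries clearly labelled
synthetic stand-ins, and real analyses should substitute literature
estimates.

**Oral paclitaxel** uses gut, liver, central and peripheral
compartments. Absorption from gut to liver follows a Weibull function
of time since the most recent dose,

`ka(t) = (BETA/ALPHA) (t/ALPHA)^(BETA-1) exp(-(t/ALPHA)^BETA)`,

with the scale `ALPHA` specific to the first versus the second daily
dose (1.68 h vs 1.97 h: ritonavir delays gastric emptying, shifting the
second dose's absorption) and the shape `BETA` specific to formulation
(2.53 for the drinking solution, 3.57 for the ASD formulations, whose
dissolution step gives a more kurtotic absorption-rate curve).

The printed Weibull expression is a *density*; applied directly as a
first-order rate constant on the gut amount (`absorption = "hazard"`,
the default and the usual nonlinear mixed-effects implementation) it
integrates to a gut-level absorbed fraction of `1 - exp(-1)` (63.2%),
with the remainder never absorbed — part of what the relative gut
bioavailability absorbs. The alternative reading, a direct
density-shaped input whose absorbed fraction is the Weibull CDF
(`absorption = "input"`), is available as a switch; both are tested
against their closed forms.

Clearance and first-pass loss use a well-stirred liver (volume fixed at
1 L, hepatic blood flow 80 L/h, unbound fraction 0.13): the intrinsic
clearance is inhibited by the current ritonavir plasma concentration,

`CLint(t) = CLint0 - Imax * C_rtv(t) / (KI + C_rtv(t))`,

an inhibitory Imax form rather than competitive inhibition because
CYP2C8-mediated metabolism continues regardless of ritonavir (the
asymptote `CLint0 - Imax` = 176 L/h is the ritonavir-insensitive
capacity). The extraction ratio is `E_H = fu CLint / (Q_H + fu CLint)`
and hepatic bioavailability `F_H = 1 - E_H`. Sampled individuals can
push `CLint` negative (`clint0 * exp(eta)` below the inhibition term);
it is floored at zero with a warning, since negative clearance is
unphysical. Formulation enters as relative gut bioavailability
(solution fixed at 1; tablet 0.97; capsule 0.46) with an additional
factor 0.59 for the second daily dose.

**TSP-1** follows an indirect-response (turnover) model at steady state
at baseline: zero-order formation `kin0 = E_BASE / turnover`,
first-order loss `kout = 1/turnover` with the turnover time fixed at
233 h (platelet survival; it is not identifiable from the data), and
paclitaxel concentration stimulating formation by
`1 + C/(EC50 + C)` — an implicit maximum of a doubling. TSP-1 is
quantified per 10^6 platelets because circulating TSP-1 is carried by
platelets.

Units are fixed package-wide: amounts in ug, volumes in L, times in h,
concentrations in ug/L (numerically equal to ng/mL), doses accepted in
mg at every interface.

## Statistical model

Between-subject variability (BSV) applies lognormally
(`P_i = P exp(eta)`) to the Weibull scale (one shared effect on both
daily-dose scales — the table reports a single ALPHA variability),
uninhibited intrinsic clearance, central volume, relative gut
bioavailability and the TSP-1 baseline; between-occasion variability
(BOV) applies to relative gut bioavailability, with every dose
administration an occasion. Residual error is proportional for both
PK and TSP-1. CV% values convert to normal SDs as `omega = CV/100`
(the usual first-order reporting convention; the exact lognormal
conversion is available via `cv_to_omega(method = "lognormal")`).

Estimation maximises a Laplace approximation of the marginal
likelihood with interaction (the residual variance follows the
individual prediction), the in-spirit equivalent of the first-order
conditional method the reference analysis used; agreement is asserted
on parameter recovery, not on objective-function values. The inner
per-subject problem is minimised by Gauss-Newton with an analytic
gradient built from a finite-difference Jacobian of the predictions
(step 1e-4), warm-started from the previous optimum with an
origin restart if it fails; the Laplace determinant uses the
linearized (Gauss-Newton/FOCE) curvature, which is positive definite
by construction and exact for linear-Gaussian subjects (verified
against the closed form). The outer problem is optimised
derivative-free (Nelder-Mead; Brent for a single parameter) on log
scale, because the marginal objective carries small
inner-optimization noise that finite-difference outer gradients
amplify. With one occasion the BSV and BOV effects on bioavailability
are folded into a single eta with summed variance (the sum of two
independent normals — identical model, fewer dimensions).

The PK -> PD sequence fixes the population PK parameters at the
PK-stage estimates. Two variants are provided, reflecting a genuinely
open choice in sequential fitting: `ppp_mode = "joint"` re-estimates
each subject's PK random effects together with the PD parameters using
both record types (BOV effects held at zero in this stage), while
`ppp_mode = "ebe"` freezes the PK random effects at their
empirical-Bayes estimates and fits the PD records alone. The `ebe`
variant exploits the structure of the turnover model: with the driver
fixed, the TSP-1 trajectory is linear in its baseline, so the
paclitaxel profile is solved once per subject and the turnover state
propagated by an exact exponential step with trapezoidal treatment of
the stimulation (grid 0.25 h; verified against the full ODE to
better than 0.1%). The recovery studies in the test suite use `ebe`;
`joint` is exercised on a smaller problem.

## Numerics

The coupled system (ritonavir, per-dose gut compartments each with its
own absorption clock, liver, central, peripheral, cumulative AUC,
TSP-1) is integrated by `deSolve::lsoda` through a compiled
right-hand side; the 1 L liver compartment makes the system stiff
(turnover ~100/h), which rules out fixed-step explicit schemes.
Exported R implementations of every right-hand side double as
documentation and as the reference the compiled path is tested
against. Default tolerances are rtol 1e-8 / atol 1e-10; dose times are
mandatory solver breakpoints, implemented as solver events (gut
deposits for paclitaxel, zero-value restart events at ritonavir dose
times). During estimation, extreme random-effect excursions can defeat
the integrator; a failed solve is retried (after a clean reset solve)
at the requested and then at relaxed tolerances, and if everything
fails the prediction is floored so the objective penalizes the
excursion as astronomically bad instead of erroring — any subject
whose final optimum sits on that floor is reported as non-converged. Per-dose gut compartments, rather than a single gut with a
reset clock, make twice-daily absorption superpose instead of
discarding unabsorbed drug at each new dose.

Exposure metrics: Cmax/Tmax from the simulation grid with local
quadratic refinement through the three points around the maximum; AUC
by trapezoid on the grid (simulation defaults use 0.05-h spacing);
time above a threshold (42.7 ng/mL = 0.05 umol/L by default, the
exposure-duration marker used for paclitaxel) by linear interpolation
of the crossings. The prediction-corrected VPC bins records by time
after the most recent dose into equal-count bins (8 by default; the
binning convention is not dictated by the source analysis) and scales
observations and simulations by the bin-median population prediction
over the record's population prediction.

## The synthetic-trial generator

`trial_design_spec()` templates emulate the three study designs:
a single 100 mg drinking-solution dose with ritonavir 30 min before
(n = 17); a two-week 30 mg solution/capsule crossover (n = 4); and the
LDM phase I design (n = 37), twice daily with a 7-h interval, capsule
daily doses 5-40 mg and tablet 40-60 mg, ritonavir 200 mg/day split
as 100 mg with each paclitaxel dose, TSP-1 sampled on days 1, 2 and 8
of cycle one and on day 1 of later cycles. The exact clinical sampling
times are not published in the main text; the generator uses a rich
0-24 h grid (0, 0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 10, 24 h after the
first daily dose) chosen to resolve the ~2 h Tmax — a fixture
convention, not a claim about the original studies. Pre-dose samples
with a true concentration of zero are emitted with the missing flag
set, because the proportional error model is degenerate at zero.
A per-subject flag controls whether ritonavir concentrations are
sampled (not all patients had ritonavir PK).

What the generator deliberately does *not* emulate: assay
quantification limits and censoring, dropout, dose interruptions or
reductions, platelet-count dynamics beyond the normalised TSP-1 unit,
and any model misspecification — the generating model is the analysis
model. Passing recovery tests therefore demonstrate that the
estimation machinery inverts the model under its own assumptions at
the study designs' information content; they do not validate the
structural model against real patients.

## Problem sizes in the test suite

Recovery studies are sized to run on a single CPU in a reasonable
time, a deliberate package choice: PK fixed-effect recovery uses 12
subjects (solution and capsule single-dose arms mixed, so the relative
capsule bioavailability is identified against the solution reference)
with the median over 3 seeded replicates compared at a 20% tolerance;
the sequential PD stage uses 18 subjects of the LDM template over 43
days with the published PD sampling days and the median over 3 seeds.
EC50 is weakly identified at metronomic concentrations (the steady-state
window of roughly 16-80 ng/mL sits well below 284 ng/mL), which is why
the reference analysis reports a 95% CI spanning 122-724 ng/mL;
single-replicate estimates are accordingly heavy-tailed, and the
recovery check is asserted on the median.

## Known limitations

- The ritonavir and IV paclitaxel plug-in values shipped with the
  package are synthetic stand-ins; absolute multi-week exposure
  quantities (e.g. steady-state Cmax and 3-week AUC of the metronomic
  regimen) are sensitive to ritonavir accumulation and should be
  recomputed with literature estimates before any substantive use.
  Quantities dominated by the oral-model parameters themselves (the
  tablet:capsule exposure ratio, absorption-driven Tmax, day-1
  exposure) are insensitive to this choice.
- No renal elimination (a minor route for paclitaxel) and no
  mechanistic CYP2C8 sub-model (absorbed into the `CLint0 - Imax`
  asymptote).
- No covariate machinery beyond formulation and daily-dose index, and
  no sampling-importance-resampling uncertainty quantification;
  standard errors are not reported.
- Laplace-with-interaction is not a bit-for-bit reimplementation of
  any specific estimation software; objective-function values are
  comparable only within this package.
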