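Package: paxpkpd
Title: Population Pharmacokinetics and Pharmacodynamics of Oral
    Paclitaxel Boosted with Ritonavir
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-physiological population pharmacokinetic and
    pharmacodynamic modelling of orally administered paclitaxel
    co-administered with the CYP3A4 inhibitor ritonavir. Implements a
    gut/liver/central/peripheral model with Weibull-function absorption
    and a well-stirred liver whose intrinsic clearance is inhibited by
    ritonavir plasma concentrations, a turnover (indirect-response)
    model for the anti-angiogenic marker thrombospondin-1, lognormal
    between-subject and between-occasion variability with proportional
    residual error, Laplace-with-interaction marginal-likelihood
    estimation with sequential PK->PD fitting, regimen simulation with
    exposure metrics (Cmax, Tmax, AUC, time above threshold),
    prediction-corrected visual predictive checks, and generation of
    synthetic trials emulating early-phase study designs.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
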