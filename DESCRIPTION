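Package: dtmdd
Title: Double Central-Peripheral Target-Mediated Drug Disposition Modelling of
    Infliximab
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Population pharmacokinetic modelling of the anti-TNF-alpha
    monoclonal antibody infliximab with target-mediated drug disposition (TMDD)
    in both the central and the peripheral compartment, under the
    quasi-steady-state (QSS) approximation. Provides the structural
    two-compartment double-TMDD model with a compiled adaptive solver and
    infusion-event handling, an exponential-interindividual-variability and
    combined-residual-error population layer with body-weight, sex and disease
    covariates, a synthetic-trial generator emulating a rich ankylosing
    spondylitis design and a sparse inflammatory-bowel-disease trough-peak
    design, marginal-likelihood estimation (Laplace with Gauss-Newton inner
    optimisation and an importance-sampling evaluator), structural-model and
    fixed-turnover-rate selection by AIC, likelihood-ratio covariate stepwise
    building, goodness-of-fit, visual-predictive-check and
    normalised-prediction-distribution-error diagnostics, and population
    simulation of TNF-alpha target occupancy (unbound/total target ratios) in
    both compartments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
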