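Package: csfpk
Title: Plasma-to-Cerebrospinal-Fluid Pharmacokinetics of Cefepime in the Rat
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compartmental pharmacokinetic modelling of cefepime transit from
    plasma to cerebrospinal fluid (CSF) in a preclinical rat study design.
    Provides linear multi-compartment models with a lag pathway into the CSF
    solved exactly by matrix-exponential propagation under multi-dose
    short-infusion regimens, a polynomial-SD multiplicative observation error
    model with likelihood and AIC machinery, nonparametric adaptive-grid
    (NPAG-style) population estimation over discrete support points, per-animal
    MAP Bayesian posterior concentration profiles on a 12-minute grid, exposure
    metrics (AUC 0-24 h, Cmax, Tmax, terminal half-life) with CSF/plasma
    penetration percentages and cohort summaries, a synthetic-study generator
    emulating the sparse staggered sampling design (including catheter failures
    and gross plasma outliers), and dataset input/output with a packaged
    per-animal exposure fixture for one-command reproduction of the study's
    summary statistics.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    lhs,
    pracma,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
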