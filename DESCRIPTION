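Package: surromed
Title: Surrogacy Assessment for Longitudinal Markers by Mediation Analysis
    in Joint Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint modeling of a longitudinal biomarker and a time-to-event
    endpoint for surrogate-endpoint validation in meta-analytic (multi-trial
    or multicenter) studies.  The longitudinal submodel is a linear mixed
    model with flexible trajectory bases; the survival submodel uses a
    penalized M-spline baseline hazard and links to the marker through its
    current level, current slope, or shared random effects.  Treatment-effect
    heterogeneity across trials enters through trial-level random or fixed
    effects.  From the fitted model the package derives counterfactual
    survival curves and the natural indirect, direct, and total treatment
    effects on the survival scale, together with the time-dependent
    proportion of treatment effect (PTE) mediated by the marker, with
    parametric-bootstrap confidence bands and the trial-level coefficient of
    determination.  A calibrated simulator with known generating parameters
    supports validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    pracma,
    splines,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
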