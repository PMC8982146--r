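Package: apzone
Title: Zone Model-Predictive Control for Automated Insulin Delivery, with an
    In-Silico Pregnancy Verification Harness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-loop glucose-control simulation toolkit built around a
    zone model-predictive controller (zone-MPC) for automated insulin delivery
    in type 1 diabetes, tuned for the tight glycemic targets of pregnancy. It
    provides a deterministic glucose-insulin-meal ODE plant with a synthetic
    virtual-patient cohort, an autocorrelated-noise CGM model, the zone-MPC
    feedback law (third-order prediction model, Luenberger observer, asymmetric
    zone cost, insulin-on-board and pump constraints), a meal/correction bolus
    calculator, a declarative scenario engine encoding a 13-scenario in-silico
    verification protocol, glycemic time-in-range metrics with consensus-target
    checks and paired statistics, and a target-zone grid-search sweep.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
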