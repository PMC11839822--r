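Package: eggwdi
Title: Egg Residue Depletion Analysis and Withdrawal-Interval Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing drug residue depletion in hen eggs after
    extra-label drug use and for estimating egg withdrawal intervals (WDIs).
    Provides non-compartmental analysis of per-hen egg-yolk residue profiles
    (observed Cmax/Tmax, best-fit terminal log-linear regression, linear
    trapezoidal AUC), Monte Carlo "virtual animal" augmentation of sparse
    timepoints to the sample sizes regulatory methods require, and three WDI
    estimators: the terminal half-life multiplier, the FDA-style 99th
    percentile / 95 percent confidence regression tolerance limit, and the
    EMA-style 95th percentile / 95 percent confidence limit on the final
    seven timepoints. A synthetic laying-flock simulator calibrated to
    topical ivermectin depletion in egg yolk supports testing and method
    evaluation when raw study data are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
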