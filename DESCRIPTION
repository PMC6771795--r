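Package: ccbias
Title: Residual Bias Diagnostics for Case-Control and Self-Controlled
    Designs in Claims Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates longitudinal administrative-claims data with known
    confounding structure and known true effects, replicates two
    retrospective case-control study designs (population-control matching
    with calipers and nested case-control with covariate adjustment) with a
    conditional logistic regression fitted from its likelihood, implements
    the self-controlled case series design (drug-era risk windows,
    pre-exposure windows, spline age and season adjustment, conditional
    Poisson likelihood), and quantifies residual bias with negative control
    exposures, covariate-balance diagnostics, and empirical p-value
    calibration.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    mgcv,
    splines,
    stats,
    utils
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
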