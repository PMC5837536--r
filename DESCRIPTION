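Package: ivbalance
Title: Bias Diagnostics Comparing Instrumental-Variable and Conventional
    Regression Analyses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Diagnostics for assessing the relative confounding bias of
    conventional (ordinary least squares) and instrumental-variable analyses
    of observational treatment studies, with a focus on physician
    prescribing-preference instruments.  Provides per-covariate bias
    components with cluster-robust confidence intervals, a modified Hausman
    difference test estimated by stacked (generalized method of moments)
    estimating equations with a clustered sandwich covariance, negative
    control outcome and negative control population tests, forest-style bias
    component plots, and simulation generators (a valid-instrument
    data-generating process, a collider-bias/selection-on-treatment process,
    and a clustered physician-preference cohort) that demonstrate when each
    diagnostic is informative.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    ggplot2,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
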