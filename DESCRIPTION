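Package: survinterim
Title: Group-Sequential Interim Analysis of High-Dimensional Survival Studies
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis framework for group-sequential interim
    analyses of survival studies with high-dimensional gene-expression
    endpoints.  Simulates two-phase (recruitment plus follow-up) microarray
    survival trials, screens genes at each interim look with univariate Cox
    proportional-hazards regression, controls the false discovery rate by
    the Benjamini-Hochberg step-up procedure without interim-specific
    alpha-spending, estimates the achieved average power rate (APR) with a
    pi0 plug-in estimator, and applies APR-threshold early stopping.  A
    Monte-Carlo replication layer aggregates per-look error and power rates
    across simulated studies; the same per-look pipeline can be applied to
    user-supplied expression and patient tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools
Suggests: testthat (>= 3.0.0), survival, withr, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
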