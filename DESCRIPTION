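Package: iuiselect
Title: Threshold-Based Selection of Couples for Intrauterine Insemination
Version: 0.1.0
Authors@R:
    person("Parc Tauli", "Reproduction Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Learns and applies extreme-value eligibility thresholds for
    intrauterine insemination (IUI) from two-period per-cycle cohort data.
    Directional cutoffs are discovered in a first recruitment period as the
    extreme value of a source group beyond which no pregnancies occur,
    checked for consistency in a second period, and turned into binary
    normal/altered covariates. Their association with clinical pregnancy is
    tested with a binomial-logistic generalized estimating equation (GEE)
    under an exchangeable working correlation with a robust sandwich
    covariance, and the significant thresholds form a decline/retain
    decision rule whose retrospective pregnancy-rate gain is evaluated.
    Includes a synthetic-cohort generator with couple-level random
    intercepts and hard outcome thresholds so the full pipeline is testable
    without patient data, plus a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
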