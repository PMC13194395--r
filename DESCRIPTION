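Package: hnet
Title: Instance-Specific Counterfactual Dose-Response Estimation with Hypernetworks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates individualized counterfactual dose-response curves for
    continuous treatments from observational data. A covariate encoder feeds a
    hypernetwork that emits the full weight vector of a small fixed-architecture
    target network mapping treatment level to outcome, trained end-to-end by
    outcome mean squared error. Includes the neural S-learner ablation baseline,
    MISE/AMSE dose-response evaluation metrics, confounded synthetic
    data-generating processes with known ground-truth oracles, and a replicate
    benchmark harness that aggregates per-instance results into mean +/- standard
    error comparison tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    arrow,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
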