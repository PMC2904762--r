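Package: rsofc
Title: Risk-Sensitive Optimal Feedback Control for Continuous Motor Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models and simulation tools for risk-sensitive optimal feedback
    control (LEQG) of a ball-steering task under Brownian force noise.
    Implements finite-horizon Riccati recursions for risk-neutral and
    risk-sensitive linear-quadratic control, Kalman filtering with
    sensorimotor delay via state augmentation, risk-sensitive certainty
    equivalence, closed-loop trial simulation with full cost accounting,
    a synthetic-subject generator for the two-noise by two-cost experimental
    design, and the behavioral analysis pipeline: lagged policy-plane
    regression, nested-model F-tests, risk-parameter inference from gain
    differences, cost decomposition, counterfactual impact-angle analysis
    and sensorimotor-delay sweeps.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
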