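Package: hebbnet
Title: Training Deep Networks with Asymmetric Feedback Connections and
    Hebbian Updates
Version: 0.1.0
Authors@R: person("hebbnet", "maintainers", email = "hebbnet@example.org",
    role = c("aut", "cre"))
Description: A from-scratch trainer for feedforward classification networks
    in which the top-down error signal travels through feedback weights R
    stored separately from the feedforward weights W. Three training modes
    are provided: ordinary back-propagation (bp), fixed random feedback
    (frfb, feedback alignment), and updated random feedback (urfb), where
    each R receives the same local Hebbian increment as its feedforward
    counterpart. Includes a saturated-linear nonlinearity, a multi-class
    hinge loss whose top-layer error signal is computable locally per
    output unit, tied convolutional and untied locally connected layers,
    max-pooling, dropout and residual-sum stages, alignment and
    filter-similarity diagnostics, a linear-network gradient-flow
    simulator, and a synthetic image generator for desk-scale experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
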