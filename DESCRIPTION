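Package: atomuq
Title: Atom-Based Uncertainty Quantification for Molecular Property Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Explainable uncertainty quantification for deep-learning molecular
    property regression. Implements a heteroscedastic directed message passing
    neural network (D-MPNN) that predicts per-atom property contributions and
    per-atom predictive standard deviations, aggregates them into molecular
    Gaussians through a fingerprint-correlation covariance model, combines
    independently trained networks with Deep Ensembles into aleatoric and
    epistemic uncertainty components, and recalibrates the aleatoric component
    post hoc by retraining only the variance layers. Ships confidence- and
    error-based calibration diagnostics (ECE, ENCE), a synthetic molecule
    generator with additive atomic ground truth, and element-keyed
    noise-injection and element-ablation experiments that probe the atomic
    uncertainty semantics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
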