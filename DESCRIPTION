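Package: mooneyrsa
Title: Dynamical Neural-Pattern Analysis of Prior-Guided Visual Disambiguation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for time-resolved multivariate analysis of sensor-level
    neural recordings in the Mooney-image disambiguation paradigm: a synthetic
    experiment generator (design scheduler, behavioral simulator, planted
    component structure in sensor epochs and ROI activation patterns),
    band-specific preprocessing, time-resolved linear decoding with temporal
    generalization, representational similarity analysis under correlation,
    cross-validated Euclidean, and single-trial separability metrics, theoretical
    model RDMs, model-driven cross-modal data fusion via commonality analysis,
    and cluster-based permutation inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    kernlab,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
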