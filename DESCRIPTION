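Package: smcca
Title: Sparse Multiple Canonical Correlation Analysis for Multimodal
    Brain-Behavior Data
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Penalized-matrix-decomposition sparse multiple canonical
    correlation analysis (sMCCA) for three aligned blocks of subject-level
    variables (white-matter tract fractional anisotropy plus EEG alpha peak
    frequency, demographics, and GO/NO-GO reaction-time distribution
    features). Provides L1-constrained multi-block component fitting with
    deflation for successive dimensions, permutation-based penalty tuning,
    permutation significance tests for pairwise canonical correlations
    (Bonferroni) and for individual variable weights (max-z family-wise
    correction), leave-one-subject-out stability selection, reduction of
    trial-level GO/NO-GO logs to reaction-time moment summaries, and a
    synthetic-data generator with planted cross-block latent structure for
    method validation at study scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
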