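Package: sparsebench
Title: Benchmarking Sparse Variable Selection in High-Dimensional Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework and method suite for benchmarking sparse
    variable selection in high-dimensional (p >> n) linear regression.
    Implements synthetic data generators with controlled design families,
    sparsity, and signal-to-noise ratio; thirteen selectors spanning
    penalized regression (lasso, elastic net, adaptive lasso), global-local
    shrinkage Gibbs samplers (Bayesian lasso, horseshoe, horseshoe+,
    regularized horseshoe), spike-and-slab models (SSVS, spike-and-slab
    lasso), sum-of-single-effects regression, and screening hybrids
    (SIS+lasso, random-forest minimum-depth screening with forward/BIC
    selection); post-processing selection rules including k-means
    binarization of posterior means; and replicated benchmark drivers with
    FDR/FNR/F-score/MSPE metrics, selection-stability profiles, and
    cross-scenario rank aggregation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    ranger,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    jsonlite,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
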