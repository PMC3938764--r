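Package: cellwiring
Title: Perturbation-Independent Causal Influence Mapping of Cell Migration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for mapping directed causal influence between
    organizational features (cell-matrix adhesion complex, F-actin and
    cell-morphology state) and behavioral output (migration speed) of
    single migrating cells, using pooled auto-regressive Granger
    causality over per-cell time series. Covers the full object-level
    pipeline: nearest-neighbor track linking and parsing filters,
    intensity standardization and local-background correction, the 29
    per-CMAC and 88 per-cell feature catalogs, Box-Cox normalization
    with normalizability screening, augmented Dickey-Fuller
    stationarity checks, subpopulation discovery (PCA, EM mixtures,
    AIC), multivariate subpopulation comparison (CVA, Mahalanobis,
    single-linkage clustering, MANOVA/Wilks, KS, KDE), feature
    selection (CVA on speed quintiles, elastic-net path ranking,
    Spearman maps), lag-grid Granger-Sargent inference with signed
    significance grids, reciprocal testing, causal-chain assembly and
    cross-condition plasticity comparison. A synthetic-data module
    generates VAR feature panels and simulated tracked-cell/CMAC
    datasets with known causal ground truth so that every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    glmnet,
    nortest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    mclust
LinkingTo:
    Rcpp,
    RcppArmadillo
Config/testthat/edition: 3
RoxygenNote: 7.3.3
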