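Package: apneaScatter
Title: Sleep Apnea Detection from Single-Lead ECG with Wavelet Scattering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Minute-epoch detection of obstructive sleep apnea from single-lead
    electrocardiogram recordings. Implements segment quality weighting from
    autocorrelation similarity, an order-2 Gabor wavelet scattering
    decomposition, a ten-measure statistical and entropy feature bank
    (moments, Shannon, approximate, sample, spectral, attention and cumulative
    residual entropy), and a random-forest classification harness with
    repeated hold-out and k-fold cross-validation, Cohen's kappa and ROC/AUC
    reporting, PCA reduction and sequential feature selection. Includes
    readers for PhysioNet-style WFDB records and delimited text, and a
    deterministic synthetic ECG generator emulating the cyclical heart-rate
    variation of apneic epochs so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    S4Vectors,
    SummarizedExperiment,
    randomForest,
    ranger,
    e1071,
    MASS,
    class,
    rpart,
    xgboost,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'ecg-io.R'
    'preprocess.R'
    'scattering.R'
    'features.R'
    'classifiers.R'
    'evaluate.R'
    'synthetic.R'
    'pipeline.R'
    'RcppExports.R'
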