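Package: gliospec
Title: FTIR Chemometrics for IDH1 Mutation Calling in Glioma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable chemometrics pipeline for calling IDH1 mutation status
    from infrared spectra of glioma tissue and patient serum. Provides spectral
    quality control (PCA score gating, Amide I intensity windows), iterative
    extended multiplicative signal correction with polynomial and Mie-type
    extinction interferents, a grid-searchable pre-processing chain
    (normalisation, binning, Savitzky-Golay smoothing and derivatives, spectral
    cuts), group-aware resampled classification (LDA, PLS-DA, random forest,
    SVM) with class-imbalance sampling and per-sample majority voting,
    Cohen's-kappa-optimised probability thresholds, ROC analysis with vertical
    curve averaging, Gini feature importance reporting, and a synthetic cohort
    generator that emulates synchrotron tissue linescans and ATR serum spectra
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    mixOmics,
    purrr,
    randomForest,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
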