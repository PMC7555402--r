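Package: cesmrad
Title: First-Order Radiomics and Discriminant Classification for
    Contrast-Enhanced Spectral Mammography
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for first-order radiomic analysis of paired low-energy
    and recombined contrast-enhanced spectral mammography (CESM) lesion
    images. Computes seven first-order gray-level statistics (mean,
    variation coefficient, gray-level range, skewness, histogram entropy,
    relative smoothness, kurtosis) on masked regions of interest of both
    image types, tests their association with hormone-receptor
    percentages, HER2 status and histological grade (Pearson and
    Mann-Whitney tests with Bonferroni adjustment), and classifies six
    binary histological/molecular outcomes with pooled-covariance linear
    discriminant analysis under leave-one-out cross-validation with
    ROC/AUC summaries. Includes a fully self-contained synthetic cohort
    generator with configurable planted feature-label effects, so the
    whole pipeline is testable without patient data, plus raster I/O for
    cohorts on disk and a reproducible end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    parallel,
    S4Vectors,
    SummarizedExperiment,
    png,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
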