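Package: pathnomo
Title: Benign-Malignant Classification of H&E Pathology Images from Colour and Entropy Statistics
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Classifies hematoxylin-eosin stained breast-pathology images as
    benign or malignant from three whole-image statistics: the mean red and
    blue channel intensities and the Shannon entropy of the grayscale
    histogram. Provides the feature extractors, cohort summary statistics and
    pooled t-tests, a 7:3 train/validation split, a multivariable logistic
    model presented as a points-scale nomogram, and a full evaluation stack
    (Mann-Whitney AUC with bootstrap confidence intervals, Hosmer-Lemeshow
    calibration test, calibration curves, decision-curve analysis). A
    synthetic-data module simulates class-conditional feature tables and
    renders RGB images with controlled channel means and entropy so the whole
    pipeline is testable without access to clinical slides.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
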