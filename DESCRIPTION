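Package: rpedetect
Title: Weakly Supervised Detection of Retropharyngeal Edema on Neck MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage detection of retropharyngeal edema (RPE) in stacks of
    axial T2-weighted water-only MRI slices. A lightweight convolutional
    slice classifier built from the contracting path of a U-Net scores each
    axial slice, and a windowed-mean-maximum aggregation rule with dual
    Youden-index thresholds turns the ordered slice probabilities into a
    patient-level label and finalized slice labels. Includes weak-annotation
    expansion (uppermost/lowermost positive slice indices to per-slice
    labels), slice standardization and training-set augmentation, repeated
    patient-wise five-fold cross-validation, slice- and patient-level
    evaluation with paired Wilcoxon comparisons, zero-padded-vector
    baselines, and a synthetic neck-phantom generator so the full pipeline
    can be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    RNifti,
    EBImage,
    pROC,
    randomForest,
    e1071,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
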