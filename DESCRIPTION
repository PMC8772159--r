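Package: breathdisc
Title: Breathomics Discrimination of Interstitial Lung Disease from GC-MS
    Volatile Organic Compound Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for untargeted exhaled-breath GC-tof-MS
    data: chromatogram preprocessing (log transform, Daubechies wavelet
    denoising, asymmetric-least-squares baseline correction, segment-wise
    retention-time alignment, probabilistic quotient normalization, peak
    picking and spectral-correlation peak merging), Random-Forest
    discrimination of subject groups with deterministic Duplex train/test
    splitting, permutation-importance VOC selection, ROC validation and
    proximity-PCA visualization, hierarchical fusion of binary classifiers
    into a single score space, regularized-MANOVA confounder testing, and
    canonical correlation of discriminatory VOCs with lung-function
    parameters with permutation inference. A synthetic-cohort generator
    with a full ground-truth ledger supports parameter-recovery testing of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    cluster,
    jsonlite,
    nortest,
    randomForest,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    mzR,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
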