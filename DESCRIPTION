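Package: apsers
Title: Recognition of Adenosine Phosphate Mixtures from SERS Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Chemometric pipeline for simultaneous recognition of AMP, ADP
    and ATP in mixed solutions from surface-enhanced Raman scattering (SERS)
    spectra under a small-data regime. Provides a synthetic SERS spectrum
    generator for adenosine phosphate mixtures, fingerprint-region
    preprocessing (quintic baseline correction, Savitzky-Golay smoothing,
    per-spectrum standardization), k-means feature selection of Raman shifts
    with elbow-method cluster-count choice and noise-cluster removal,
    training-data augmentation by group-conditional Gaussian noise injection
    and SMOTE interpolation, and a benchmark of seven classifier families
    (LR, DT, kNN, LDA, SVM, RF, MLP) under raw, feature-selected and
    augmented training conditions with a train/test swap protocol.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    MASS,
    class,
    nnet,
    rpart,
    ranger,
    e1071,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
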