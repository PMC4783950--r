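Package: golgiCSP
Title: Golgi-Resident Protein Type Prediction with Common Spatial Patterns
    Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Feature extraction and classification pipeline for
    discriminating cis-Golgi from trans-Golgi resident proteins from
    sequence and evolutionary information.  Implements g-gap dipeptide
    composition, three PSSM-derived 20x20 evolutionary descriptors (PSSM
    dipeptide composition, bi-gram PSSM and evolutionary-difference PSSM),
    a two-class Common Spatial Patterns projection that compresses each
    descriptor to 20 normalized log-variance features, SMOTE oversampling
    for class imbalance, random-forest recursive feature elimination, and
    a random-forest classifier evaluated with sensitivity, specificity,
    accuracy, Matthews correlation and ROC/AUC under k-fold and jackknife
    cross-validation.  Includes a seeded synthetic two-class sequence and
    PSSM generator with controllable class separation so the whole
    pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
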