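Package: plantDBP
Title: Lineage-Specific Prediction of DNA-Binding Proteins from Amino
    Acid Composition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds and applies lineage-specific support vector machine
    models for predicting DNA-binding proteins from amino acid
    composition alone. Provides curated training-set construction from
    Gene Ontology evidence (term closures over is_a edges, evidence-code
    filtering), BLASTclust-style homology reduction at configurable
    identity and coverage thresholds, balanced and class-imbalanced
    (realistic) dataset assembly, RBF-kernel SVM training with grid
    search over cost and gamma and seeded Platt-style probability
    calibration, five-fold cross-validation with accuracy, sensitivity,
    specificity and Matthews correlation coefficient, and proteome-scale
    application: probability-threshold sweeps with expected-fraction
    threshold selection, annotation-class comparison, nuclear
    localisation enrichment, and Gene Ontology term enrichment using
    Fisher's exact test with false discovery rate correction. A seedable
    synthetic proteome generator with controlled compositional class
    separation supports end-to-end testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    graphics,
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    kernlab,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
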