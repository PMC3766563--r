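Package: antioxseq
Title: Antioxidant Protein Prediction from Sequence Composition
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identification of antioxidant proteins from primary sequence.
    Proteins are encoded as 420 normalized composition features (20 amino
    acid frequencies plus 400 overlapping dipeptide frequencies), reduced
    by correlation-based feature-subset selection (CFS) with best-first
    search over symmetrical-uncertainty correlations of MDL-discretized
    features, and classified by a naive Bayes log posterior-odds score with
    a tunable decision threshold. Evaluation supports jackknife
    (leave-one-out) and stratified k-fold cross-validation with
    sensitivity, specificity, accuracy, ROC curves and auROC. A seeded
    synthetic-sequence generator with class-dependent residue and
    dipeptide biases supports end-to-end testing, and a command-line
    interface ties the pipeline together.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
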