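Package: smiReg
Title: Predicting Small-Molecule Regulation of miRNA Expression
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting whether a small molecule up- or
    down-regulates the expression of a mature miRNA. miRNAs are encoded as
    277-dimensional sequence-composition descriptors (length, mononucleotide
    ratios, 2-mer and 4-mer frequencies) and small molecules as 166-key MACCS
    structural fingerprints. Credible negative training pairs are mined with a
    similarity-propagated regulation score (mean Tanimoto to a miRNA's known
    regulators), balanced against curated positives, and used to train binary
    classifiers (regularized logistic regression, k-nearest neighbours,
    RBF-kernel support vector machine, single-hidden-layer neural network and
    random forest) with five-fold cross-validated hyperparameter tuning by
    AUC and F1-calibrated decision thresholds. Includes batch prediction in
    four query modes (rank molecules for a miRNA or miRNAs for a molecule,
    under either regulation direction), a synthetic-corpus generator with
    planted fingerprint-family by sequence-motif structure for end-to-end
    testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    FNN,
    glmnet,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with RDKit, available as 'python' on
    the PATH (used only for SMILES parsing and MACCS fingerprint
    computation; fingerprint-level workflows run without it)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
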