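Package: synergat
Title: Graph-Attention Prediction of Drug Combination Synergy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts synergistic versus antagonistic drug combinations on
    cancer cell lines from drug structures and cell-line gene expression. Drugs
    given as SMILES strings are converted to molecular graphs and encoded with a
    multi-head graph attention network; an adaptive cross-drug attention module
    scores every atom of one drug against all atoms of its partner and pools the
    pair into graph-level embeddings; cell lines are embedded from a TPM-normalized
    expression panel with a tanh multilayer perceptron; the three embeddings are
    fused through a gated (highway-style) interaction controller and classified
    by a softmax head. Training minimizes a dual-pass cross-entropy objective with
    a symmetric Kullback-Leibler consistency term between two dropout passes.
    Includes Loewe-additivity labeling, stratified cross-validation, the full
    classification metric set (AUROC, AUPR, accuracy, balanced accuracy,
    precision, sensitivity, specificity, Cohen's kappa), per-atom attention
    reports for substructure interpretation, and a synthetic-data generator so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
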