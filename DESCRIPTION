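Package: DrugVNN
Title: Ontology-Structured Visible Neural Networks for Drug Sensitivity
    Prediction
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts dose-response AUC of cancer cell line / drug pairs with
    an interpretable two-branch model: a visible neural network (VNN) whose
    layers are compiled from a biological-process ontology over fused
    multi-omic genotypes (mutation, expression, copy number), and a
    feed-forward branch over 2048-bit Morgan fingerprints of drug structures.
    The branches are trained jointly against AUC with a root-plus-auxiliary
    squared-error objective, and trained models are interpreted through the
    RLIPP subsystem-importance score and 2-D genotype/drug embeddings. A
    synthetic-cohort generator with a planted gene-set x drug-bit response
    mechanism makes the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ChemmineR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
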