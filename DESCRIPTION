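Package: rnabindpred
Title: Sequence-Based Prediction of RNA-Binding Residues in Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage sequence-based prediction of RNA-binding residues.
    A homology component transfers experimentally determined protein-RNA
    interface annotations from solved complexes to a query protein, with
    homologs weighted by an interface-conservation score predicted from
    BLAST alignment statistics via a linear model and stratified into
    Safe/Twilight/Dark reliability zones. A machine-learning component
    classifies residues with an RBF-kernel support vector machine over
    sliding windows of position-specific scoring matrix profiles, tuned by
    grid search under sequence-based cross-validation. A second-stage
    logistic regression combines the two scores, handling residues the
    homology component cannot cover, so every residue of every query
    receives a prediction. Includes structure-based interface labeling
    (5 Angstrom heavy-atom rule), dataset curation filters, per-residue
    evaluation metrics (MCC, ROC/PR), and deterministic synthetic-data
    generators so the full pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    bio3d,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    xml2
Config/testthat/edition: 3
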