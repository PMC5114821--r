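Package: ligbind
Title: Ligand-Specific Prediction of Protein-Ligand Binding Residues
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Sequence-based prediction of ligand binding residues with a
    ligand-specific strategy.  Residues are encoded from position-specific
    scoring matrices, predicted structure properties and two layers of
    evolutionary conservation (per-position relative entropy and
    Jensen-Shannon divergence, plus a position-weight-matrix segment score),
    and classified by a class-imbalance-aware boosted ensemble of radial
    basis function kernel classifiers in which only the non-binding class is
    resampled and reweighted.  Also provides a structure-derived binding
    residue labeler based on the van der Waals contact criterion, a consensus
    combiner over component predictor outputs, grouped cross-validation and
    confusion-matrix metrics, and synthetic fixture generators so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
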