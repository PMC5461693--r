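Package: sgdesign
Title: Sequence, Thermodynamic and Structural Features for CRISPR sgRNA
    On-Target Efficiency Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes eight classes of candidate features for single guide RNA
    (sgRNA) on-target efficiency from a 40 bp (or 30 bp) genomic target context:
    position-dependent mono- and dinucleotide one-hot encodings, spacer
    nucleotide frequencies, nearest-neighbor thermodynamics and secondary
    structure scalars (melting temperature, GC, entropy/enthalpy/free-energy
    change, homopolymer runs, repeats, stem-loops, minimum folding energy),
    table-driven structural and physiochemical property summaries, pseudo
    k-tuple nucleotide composition (PseKNC), and Needleman-Wunsch alignment
    scores between the PAM-proximal seed and the sgRNA scaffold. Provides an
    elastic-net classifier of sgRNA efficiency with three evaluation protocols
    (repeated 3-way cross-validation, cross-dataset, leave-one-gene-out),
    exhaustive feature-class combination sweeps, single-feature ranking by BIC
    and AUC, Youden-index operating points, DeLong tests for correlated ROC
    curves, and a synthetic data generator with planted sequence effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    pROC,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse,
    withr
Config/testthat/edition: 3
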