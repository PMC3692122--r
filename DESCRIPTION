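Package: ConsensusQA
Title: Consensus Quality Assessment of 3D Protein Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Clustering (consensus) quality assessment for predicted 3D
    protein structures. Given a target sequence and a pool of candidate
    models, computes per-model global quality scores by combining
    TM-score-based structural superposition with an alignment-free
    distance-matrix Q-score, converts mean per-residue S-scores into
    predicted distances from the native structure, calibrates P-values
    that a model is incorrect against a null distribution of scores of
    known-incorrect models, and writes CASP QA (QMODE1/QMODE2) files and
    B-factor-annotated PDB models. Includes a quasi-single-model mode in
    which one submitted model is pooled with a reference model set, and a
    synthetic decoy generator for benchmarking and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    graphics,
    grDevices,
    utils,
    bio3d,
    Biostrings,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
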