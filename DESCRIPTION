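Package: m5ugraph
Title: Prediction of RNA 5-Methyluridine Sites from Sequence and Graph
    Embedding Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies 5-methyluridine (m5U) sites in RNA from fixed-length
    41-nt sequence windows centred on a uridine. Seven sequence-derived
    feature encoders (k-spaced nucleotide pair spectrum, composition/
    transition/distribution, Bi-profile Bayes, electron-ion interaction
    pseudopotential, pseudo k-tuple nucleotide composition, nucleotide
    chemical properties with cumulative density, and position-specific
    nucleotide pair propensities) are fused with graph-embedding features
    learned from a fast linear-neighborhood similarity network over the
    samples (SocDim modularity eigenvectors, Node2Vec biased random walks
    with skip-gram, and GraRep k-step transition SVD). A gradient-boosted
    tree classifier is trained on the fused representation, with holdout,
    k-fold cross-validation and cross-group evaluation protocols, and a
    synthetic-data generator with a planted centre-flanking motif so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    withr,
    xgboost,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
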