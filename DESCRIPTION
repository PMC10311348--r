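Package: sigpept
Title: Transformer-Based Signal Peptide and Cleavage Site Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-to-sequence prediction of signal peptides from protein
    N-terminal sequence. A transformer encoder-decoder labels every residue
    with one of eight classes (five signal-peptide types cleaved by signal
    peptidases I, II and IV on the Sec and TAT pathways, plus intracellular,
    transmembrane and extracellular), from which the signal-peptide type and
    the cleavage site are derived. Includes a grammar-based generator of
    labeled synthetic sequences with the canonical tripartite architecture
    (basic N-region, hydrophobic H-region, polar C-region, twin-arginine
    motif, lipobox followed by cysteine), teacher-forced training with
    stochastic weight averaging, greedy autoregressive decoding,
    tolerance-windowed cleavage-site precision/recall/F1, per-class Matthews
    correlation with two negative-set definitions, expected calibration
    error, a learning-curve harness, and gradient-based input-importance
    (saliency) analysis with motif-aligned averaging.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
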