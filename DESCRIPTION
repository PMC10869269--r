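Package: foldscan
Title: Structure Search with a Learned Tertiary-Interaction Alphabet
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Research-scale protein structure search. Encodes per-residue
    tertiary interactions as a learned 20-state structural alphabet via a
    vector-quantized autoencoder, searches structure sets with a similar
    k-mer double-diagonal prefilter and combined amino-acid/structural-state
    Smith-Waterman alignment, and calibrates hits with LDDT- and
    TM-score-based structural bit scores, Gumbel extreme-value E-values and
    a two-gamma mixture true-positive probability. Includes the full
    training pipeline (alphabet, substitution matrix, E-value model) and a
    synthetic-structure generator so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
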