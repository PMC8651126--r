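Package: viratax
Title: Comparative Genomics and Taxonomy of Tailed Archaeal Viruses
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Gene-sharing taxonomy for tailed archaeal virus genomes:
    exact Smith-Waterman protein homology with Karlin-Altschul E-values,
    protein clustering, composite generalized Jaccard (CGJ) genome
    distances with UPGMA family demarcation and shared-protein genus
    demarcation, distance-based adhesin phylogenetics, efficiency-of-plating
    host-range analysis (normalization, log10 binning, host-range
    similarity, adhesin association), restriction-motif frequency and
    Markov-null depletion diagnostics, provirus detection with
    attachment-site direct repeats, and seeded synthetic-data generators
    so every stage runs without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
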