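Package: tcrclone
Title: Clonotype Graphs and Sharing Statistics for Paired Single-Cell TCR Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of paired-chain T cell receptor (TCR) repertoires from
    single-cell sequencing. Builds an undirected chain-pairing graph from
    per-cell TRA/TRB junction observations and calls clones as its connected
    components; classifies junctions as expanded (seen in two or more cells)
    and public (seen in more than one donor) versus private; compares donor
    groups by iterative downsampling with Simpson/Shannon diversity and
    junction-length statistics; tests sequence convergence of TRB junctions
    that share a TRA chain against resampled Levenshtein-distance null sets;
    and scores junction generation probability (pgen) under a simplified,
    exactly-computable V(D)J recombination model, with import of externally
    computed pgen values. A synthetic repertoire generator with ground truth
    makes every analysis testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Biostrings,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
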