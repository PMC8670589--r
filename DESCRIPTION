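Package: plastcomp
Title: Comparative Analysis of Chloroplast Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of quadripartite chloroplast
    genomes (plastomes): automated detection of the large single copy, small
    single copy and inverted repeat regions with per-region size and GC
    statistics; microsatellite (SSR) scanning under MISA-style unit-length
    thresholds; REPuter-style detection of forward, reverse, complement and
    palindromic oligonucleotide repeats; anchored global alignment of
    near-identical genomes with extraction of substitution and InDel events
    and transition/transversion classification; per-gene Ka/Ks estimation by
    the Nei-Gojobori (1986) counting method with Jukes-Cantor correction;
    codon-usage and amino-acid-frequency profiling; characterization of genes
    at the single-copy/inverted-repeat junctions; and binned correlation and
    co-occurrence analysis of mutational events along the genome. A synthetic
    plastome generator with ground-truth logs supports closed-loop testing of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
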