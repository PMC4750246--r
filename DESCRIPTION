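Package: dbgvar
Title: Assembly-Free Variant Discovery and Read-Set Comparison via k-mer
    de Bruijn Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-free analysis of raw short-read sequencing data
    through a shared kernel: canonical k-mer counting, a solidity filter,
    an optional bloom-filter membership structure, and an implicit de
    Bruijn graph whose edges are computed by membership queries. On top of
    the kernel the package detects isolated-SNP bubbles and quantifies
    them by read map-back with a phi (normalized chi-squared) score,
    detects inversion breakpoints from their four 2k-length breakpoint
    words, performs starter-anchored targeted assembly with a JSON
    neighborhood graph, and compares whole read sets via shared-k-mer bit
    vectors, similarity matrices and average-linkage dendrograms. A
    bundled simulator plants isolated SNPs and inversions in random
    genomes and scores recall and precision against the planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    jsonlite,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
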