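Package: mitophylo
Title: Mitogenome Characterization and Distance-Based Phylogenetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy tools for characterizing annotated mitochondrial genomes and
    placing them in distance-based phylogenies. Parses GenBank flat files and
    tab-separated feature tables into a mitogenome object, computes per-gene and
    whole-genome base composition with AT/GC strand skews and feature-class
    length roll-ups, tallies codon usage and relative synonymous codon usage
    (RSCU) under the vertebrate mitochondrial code (including incomplete stop
    codons completed by polyadenylation), and estimates pairwise genetic
    distances (p-distance, closed-form Tamura-Nei 1993, and maximum composite
    likelihood TN93) from concatenated protein-coding gene supermatrices,
    with neighbor-joining trees and nonparametric bootstrap support. A
    simulation module generates random trees, TN93-evolved alignments, and
    synthetic annotated circular mitogenomes with known ground truth, and a
    morphometrics helper checks specimen measurements against published
    species reference ranges.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
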