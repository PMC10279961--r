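Package: plastidscan
Title: Comparative Plastome Structure, Diversity Scanning, and DNA Barcode Mining
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for comparative analysis of circular plastid genomes and for
    mining lineage-diagnostic DNA barcodes. Detects the quadripartite
    architecture (LSC, SSC, and the two inverted repeats) of circular
    plastomes, computes sliding-window nucleotide diversity and site-class
    summaries on multiple alignments, identifies group-diagnostic fixed
    substitutions, mines candidate barcode regions under length, variability
    and conserved-flank constraints, delimits products by in-silico PCR, and
    tests species or lineage discrimination with neighbor-joining trees and
    nonparametric bootstrap monophyly support. A synthetic plastome generator
    with a recorded ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    jsonlite,
    phangorn,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
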