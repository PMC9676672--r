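Package: plectax
Title: Taxonomic Resolution Analysis for DNA-Barcoded Nematode Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to reproduce and generalize a reverse-taxonomy workflow
    for the nematode genus Plectus: uncorrected pairwise distances
    (p-distances) from fixed-length barcode alignments, neighbor-joining
    trees with column-resampling bootstrap supports, delimitation of COI
    haplotype groups by a three-criterion rule (bootstrap support,
    within-group distance ceiling, nearest-neighbor separation),
    within/between-group distance summaries, morphometric ratio
    classification of short- and long-tailed morphotypes, comparison of
    marker resolution between COI and 18S partitions, and matching of
    metabarcode OTUs to Sanger reference sequences.  A seeded simulator
    generates alignments with known cluster structure, companion low
    resolution 18S sequences, and two-morphotype measurement tables so
    that every stage of the analysis is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    mclust,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
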