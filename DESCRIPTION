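Package: periscan
Title: Discovery and Characterization of Intronless Genes at Pericentromeric Repeats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for discovering and characterizing
    transcription-competent intronless genes embedded in pericentromeric
    repeat sequence ("GPS" genes). Identifies candidate loci by intersecting
    centromere-flanking windows, repeat annotations and histone-mark
    (H3K27ac/H3K27me3) signal tracks; finds open reading frames in all six
    frames with alternative initiation codons and annotates the encoded
    proteins (length, approximate molecular weight, isoelectric point,
    residue enrichment); aligns transcript sequences back to the genome to
    establish intronless status and call codon-level silent, missense and
    stop-gain mutations; builds pairwise percent-identity matrices, UPGMA
    cladograms, conserved-window and FPFP-motif scans over a gene family;
    and scores expression with the maximum-read-at-single-point (MRSP)
    statistic, integrates C19MC miRNA expression, selects matched
    positive/negative cell-line groups and screens for differential
    expression. Ships a fully seeded synthetic-genome generator with a
    ground-truth ledger so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
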