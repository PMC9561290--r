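Package: utrtile
Title: Dense-Tiling MPRA Design and Analysis for RNA Localization Elements
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for massively parallel reporter assays (MPRAs) that densely
    tile 3' UTRs to locate RNA localization elements (zipcodes). Covers oligo
    pool design from transcript annotations (meta-UTR merging, inclusion
    filters, 260-nt / 4-nt-step tiling with flank extension), simulation of
    the full assay (synthetic UTRs with planted A/G-rich elements,
    negative-binomial soma/neurite count matrices, error-bearing paired-end
    reads with unique molecular identifiers), quantification of reads into
    per-oligo UMI counts (adapter trimming, seed-indexed read assignment,
    UMI deduplication), per-oligo neurite-vs-soma enrichment statistics with
    false discovery rate control, contiguous active-window ("oligonucleotide
    union") calling with intersections and peak oligos, and sequence-feature
    characterization (nucleotide composition, A/G-rich window scanning, kmer
    enrichment, G-quadruplex flags).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
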