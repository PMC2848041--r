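Package: retrokit
Title: Structural Annotation and Evolutionary Analysis of Non-LTR Retroelement Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for annotating small families of non-autonomous non-LTR
    retroelements (SINE-like retroposons such as the Arabidopsis Sadhu family)
    directly from genomic sequence. Implements structure-based element
    discovery (5' consensus motif, polypyrimidine patch, 3' poly(A) tract),
    detection of target site duplications under the target-primed reverse
    transcription (TPRT) staggered-cut model with nicking-site consensus
    profiles, subfamily classification and nomenclature (family, derived and
    "like" elements), uncorrected-distance neighbor-joining trees with
    bootstrap support, iterative homology-closure discovery of family members
    in new genomes, filled/empty insertion-site genotyping across strain
    panels, and a seeded TPRT insertion simulator with machine-readable
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
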