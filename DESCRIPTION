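Package: mirtraj
Title: miRNA Expression Trajectories and Cluster Contributions from Small
    RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable pipeline for profiling microRNA expression across a
    stem-cell differentiation series (human embryonic stem cells,
    self-renewing neural stem cells, and differentiating neural stem
    cells). Implements small-RNA read filtering (adapter trimming,
    quality and length filters, contaminant exclusion by mismatch
    priority) and read-to-miRNA counting; median-of-ratios
    normalization, abundance filtering, and a negative-binomial Wald
    test with Benjamini-Hochberg correction for the two developmental
    contrasts; classification of miRNAs into eight expression-trajectory
    groups; and analysis of the contribution of genomic miRNA clusters
    and seed-defined families to the miRNA population, including
    seed-similarity reports. A synthetic-data module generates
    references, FASTQ reads, and count matrices with planted structure
    so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    withr,
    yaml
Suggests:
    DESeq2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
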