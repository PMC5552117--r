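Package: aschip
Title: Allele-Specific Chromatin State and Expression Skew Analysis
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of allele-specific ChIP-seq and RNA-seq data from F1
    hybrid cells: assignment of sequenced fragments to parental haplotypes
    from per-haplotype alignment scores, fragment deduplication and counting
    over promoter and gene-body regions, exact binomial tests of allelic
    skew with Benjamini-Hochberg FDR control, classification of composite
    and per-allele chromatin states (silent, bivalent, active) from H3K4me3
    and H3K27me3 densities, and prediction of allelic expression skew from
    allelic chromatin mark densities via summed log Bayes factors.  Includes
    a seeded synthetic-data generator emulating the statistical structure of
    hybrid mouse embryonic fibroblast data for end-to-end validation, and a
    command-line interface binding the pipeline stages into reproducible
    runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
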