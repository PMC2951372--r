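Package: tilemark
Title: Tiling-Array Histone-Mark Scoring, Domain Calling and Endosperm
    Epigenome Analysis
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for ChIP-chip tiling-array profiling of
    H3K27me3 in the Arabidopsis endosperm: probe standardization within
    affinity bins, sliding-window MAT-style enrichment scores against dual
    controls, enriched-region calling with minimum-run and maximum-gap
    constraints, gene-level target assignment and shared versus
    endosperm-specific classification, metagene and chromosomal profiling,
    transposon-superfamily and functional-category enrichment by
    hypergeometric tests with Benjamini-Hochberg correction, DNA-methylation
    stratification by target class, rank-product differential expression with
    permutation-based false discovery rates, qPCR relative-expression
    arithmetic, and Mendelian seed-class expectations for maternal-effect
    crosses. Includes a seeded synthetic-data generator that emulates every
    input with embedded ground truth, so the whole pipeline is testable
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
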