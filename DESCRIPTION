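Package: enhancerscape
Title: Enhancer Modality Classification and Regulatory Landscape
    Integration for Two-State Cell Transitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrates ATAC-seq, H3K4me1 and H3K27ac ChIP-seq peak sets,
    replicate RPKM expression matrices and significant Hi-C interaction
    tables for a two-state cell transition. Identifies condition-specific
    enhancers (H3K4me1+/H3K27ac+/ATAC+ in the induced state, H3K27ac
    acquired), classifies their prior-state activation modality
    (accessible, poised, unmarked, de novo), links enhancers to their
    nearest transcription start site, intersects differential expression
    with promoter accessibility change, and nominates candidate
    enhancer-promoter pairs from chromatin loops that are present in some
    conditions and absent in others. Ships a seeded synthetic multi-omic
    study generator with planted ground truth so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
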