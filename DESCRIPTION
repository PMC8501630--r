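Package: cnacomplexity
Title: Genomic Complexity Scoring and Cis-Expression Integration for
    Allele-Specific Copy Number Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of allele-specific copy number
    segmentations of tumor genomes (ASCAT-style segment tables).
    Computes length-weighted-median tumor ploidy, calls each segment
    gained or lost relative to ploidy, builds cross-sample aberration
    frequency tracks and extracts recurrent aberrant regions, compresses
    each profile into eight genomic-complexity indices (variation,
    steepness, curvature, ploidy deviation, gain, loss, LOH and allelic
    asymmetry) genome-wide and per chromosome arm, compares the indices
    between sample strata with normality-gated tests and Bonferroni
    correction, integrates copy number with gene expression to identify
    cis-regulated genes, and runs Fisher gene-set enrichment over the
    cis-gene list. Ships a synthetic cohort generator that emulates
    allele-specific segment output with configurable aberration rates,
    multimodal ploidy and known cis effects, with full truth tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
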