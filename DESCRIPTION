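Package: stalkscape
Title: Spatiotemporal Stalk Transcriptome and SELEX Regulatory Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for spatiotemporal analysis of grass stalk
    internode transcriptomes: high-variation gene selection by median absolute
    deviation, developmental-zone assignment by hierarchical clustering and PCA,
    fuzzy c-means expression clustering, a from-scratch weighted gene
    co-expression network (soft-threshold selection, topological overlap,
    dynamic tree cut, module eigengenes, module-trait statistics and hub
    extraction), transcription-factor family summaries, HT-SELEX 10-mer
    enrichment with seed-based motif construction, and genome-wide promoter
    affinity scanning. A synthetic-data generator with known ground truth
    emulates the study design (19 internodes in four stages, two replicates)
    and provides end-to-end parameter-recovery checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    tools,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
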