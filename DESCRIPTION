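Package: methRisk
Title: Bin-Level Capture Methylome Differential Analysis and Transcriptome
    Integration for Tissue Risk Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Differential DNA methylation analysis for enrichment-based
    (MethylCap-seq) capture methylomes using fixed 250-bp bins scored as
    region-relative z-scores, with group comparison by delta-Z and Z-ratio
    statistics, Welch t-tests and Benjamini-Hochberg FDR control, genomic
    feature annotation, a count-based differential expression arm with
    median-of-ratios normalization, methylation-expression Pearson
    integration, signature overlap and candidate prioritization, paired
    two-timepoint enhancement analysis, and a synthetic data generator that
    emulates a two-risk-group breast tissue study design with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
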