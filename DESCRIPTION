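Package: stressomics
Title: Integrative Proteome-Transcriptome Analysis of Metabolite Stress in
    Clostridia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for integrating iTRAQ quantitative proteomics with bulk
    transcriptomics (RNAseq counts and microarray log-ratios) in bacteria
    under metabolite (butanol/butyrate) stress. Implements ratio
    normalization and SAM-style permutation testing with delta-threshold FDR
    control, a five-category protein classifier with sentinel display values
    for exclusive detection, percentile abundance ranking, TSS calling from
    TEX-enriched strand-specific coverage with 5'UTR length and leaderless
    transcript annotation, Shine-Dalgarno RBS strength scoring, and
    discordance/hypothesis screens that flag post-transcriptionally regulated
    genes. Ships a synthetic multi-omic data generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    BiocGenerics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
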