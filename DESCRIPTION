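Package: mrrbsim
Title: Simulation and Coverage Analytics for Multiplexed Reduced-Representation
    Bisulfite Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates and evaluates reduced-representation bisulfite sequencing
    (RRBS) experiments end to end: in silico MspI digestion of real or synthetic
    genomes, gel-based and gel-free fragment size selection, barcoded
    multi-sample bisulfite read simulation with optional PCR template-switch
    chimeras, an MspI-end-anchored bisulfite-aware read mapper with per-CpG
    methylation calling, CpG island/shore/promoter/tile feature annotation, and
    the coverage-depth, conversion-efficiency, replicate-correlation and
    chimera quality-control analytics used to benchmark gel-free multiplexed
    protocols against gel-based RRBS.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    data.table,
    Rcpp,
    withr,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
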