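Package: umeseq
Title: Simulation and Analysis of Unmethylated-CpG Enrichment Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A generative simulator and analysis pipeline for enzymatic
    unmethylated-CpG enrichment sequencing assays. Simulates synthetic
    genomes with CpG islands, isolated sites and CpG-free gaps, per-CpG
    methylation profiles with planted cell-type markers and differential
    regions, spike-in oligos, and the capture workflow itself
    (fragmentation, enzymatic tagging, saturating bead binding, elution,
    duplication). Provides the downstream analyses: CpG site catalogs and
    region classes, RPGC/RPKM coverage tracks, enrichment-fold statistics,
    beta-binned signal ratios, saturation and correlation analyses,
    change-point DMR segmentation with a negative-binomial Wald test,
    tissue-marker scoring matrices, and tumor-informed cell-free DNA
    scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    withr,
    data.table,
    Rcpp,
    Biostrings,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
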