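Package: clockdissect
Title: Functional Dissection of Blood Epigenetic Clocks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to dissect what CpG-based epigenetic age predictors
    ("clocks") measure in whole blood. Applies linear CpG clocks with their
    published transforms, quantifies cross-clock redundancy (shared CpGs,
    correlated proxies, genomic-feature enrichment), maps associations
    between clock-CpG methylation and genome-wide gene expression in cis
    and in trans with latent-factor adjustment and per-CpG empirical-null
    correction, selects and clusters a core trans-association set, relates
    the clusters to sorted immune-cell references via paired
    naive-versus-activated age-prediction deltas, and cross-checks trans
    pairs against meQTL/eQTL catalogs. Includes a synthetic whole-blood
    cohort generator in which clock-CpG methylation and marker-gene
    expression are both driven by age-dependent naive/activated T- and
    NK-cell proportions, so the entire pipeline is testable with known
    ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
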