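Package: mmaomics
Title: Multi-Omics Severity, Association and Anaplerosis Analytics for
    Methylmalonic Aciduria Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for multi-layered omics studies of
    methylmalonic aciduria (MMA) and related inborn errors of metabolism.
    Implements a clinical severity score and phenome-wide marker screen,
    mixed-model differential expression with an expression-derived sample
    kinship (EMMA-style single eigendecomposition, REML variance-ratio
    profiling, BLUP-based sample ranking), transcript-protein differential
    correlation with a diagonal-distance statistic, [U-13C]glutamine
    isotopologue analytics including a discrete-turn TCA label-propagation
    simulator and reductive-fraction estimation, affinity-purification MS
    bait-prey specificity filtering with ANOVA enrichment and network
    export, and rule-based rare-disease variant triage. A seeded synthetic
    cohort generator reproduces the statistical structure every stage
    assumes, so the full pipeline is testable without restricted patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
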