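Package: grslife
Title: Gene-Environment Interaction Analysis of Body Fat Mass Change
Version: 0.1.0
Authors@R:
    person("GRS", "Lifelog Team", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for studying how genetic background
    modulates the effect of lifestyle change on body fat mass (BFM).
    Provides SNP-level genotype quality control (call rate, minor allele
    frequency, exact Hardy-Weinberg test), extraction of lifestyle-change
    deltas from daily diet and activity diaries, per-SNP gene-environment
    interaction regression, interaction-weighted genetic risk scores
    (GRS-C, GRS-F, GRS-E for carbohydrate, fat and exercise change),
    data-driven high/low GRS stratification with Benjamini-Hochberg FDR
    control, and a four-group (GRS by lifestyle-compliance) ANOVA layer.
    A synthetic-cohort generator with planted interaction effects makes
    the whole pipeline testable without access to any real cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    GenomicRanges,
    jsonlite,
    S4Vectors,
    stats,
    SummarizedExperiment,
    tools,
    utils,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
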