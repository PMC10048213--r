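Package: drmeta
Title: Evidence Synthesis for Diabetic Retinopathy GWAS Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for synthesizing genome-wide association
    evidence on diabetic retinopathy and its subphenotypes: curation and
    significance tiering of reported GWAS signals, cross-study overlap
    detection (identical rsIDs and proximity within a base-pair window),
    allelic-model effect extraction from genotype counts or reported
    confidence intervals, DerSimonian-Laird random-effects meta-analysis
    with heterogeneity, leave-one-out sensitivity and funnel diagnostics,
    Hardy-Weinberg and study-quality gating, and linkage-disequilibrium
    proxy selection with local functional-annotation joining. A seeded
    synthetic-data module generates case-control cohorts with a specified
    allelic odds ratio, control allele frequency and between-study
    heterogeneity so the full pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    optparse
Config/testthat/edition: 3
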