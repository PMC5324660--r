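Package: varwarden
Title: Cohort Variant Warehouse for Clinical Sequencing Interpretation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unified management of sequencing variants and per-patient
    clinical data for clinical gene-panel cohorts. Imports single-sample
    VCF files into a deduplicated variant registry, exports and re-imports
    ANNOVAR-style annotation tables, applies a configurable rare-variant
    filtering cascade, computes inheritance-mode-stratified case-control
    odds ratios (Woolf confidence intervals, Fisher exact tests,
    Haldane-Anscombe zero-cell correction) for PS4-style evidence
    flagging, aggregates carrier phenotypes (mean, standard deviation,
    z-scores) at the variant or gene level, and combines ACMG/AMP
    evidence codes into a pathogenicity classification. Includes a
    seeded synthetic-cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
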