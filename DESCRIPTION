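Package: clinwgs
Title: Downstream Interpretation Toolkit for Rare-Disease Whole-Genome Sequencing
Version: 0.1.0
Authors@R:
    person("GMC", "Toolkit Authors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Bespoke downstream stages of a clinical rare-disease WGS
    workflow: deduction of compatible Mendelian inheritance models from
    pedigrees (including de novo sub-models and compound-heterozygote
    pairing), configurable weighted-sum variant rank scoring, a local
    observation database for cohort-specific frequency and artifact
    annotation, gene-panel and HPO-driven in-silico filtering, criteria-based
    triage of variants for secondary (Sanger) confirmation, family-level QC
    (trio concordance, SNP fingerprinting, uniparental-disomy screening,
    STR expansion classification), transcript coverage completeness
    reporting, and cohort-level diagnostic-yield statistics. A deterministic
    synthetic-fixture generator makes every stage testable without access to
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
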