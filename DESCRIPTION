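Package: sfscreen
Title: Secondary-Findings Screening of Exome Cohorts in ACMG Actionable Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the frequency of medically actionable secondary findings
    and of recessive-disease carriers in an exome-sequenced cohort screened
    against the ACMG v3.2 list of 81 actionable genes. Provides a synthetic
    cohort generator with planted variants and known ground truth, census-based
    stratified resampling of diagnostic cohorts, genotype quality-control and
    anonymized multi-sample aggregation of per-individual VCFs over gene
    regions, a prioritized pathogenicity-screening cascade (internal
    laboratory classifications, ClinVar review-star assertions, population
    allele-frequency cutoff with exception list, molecular-consequence
    impact), merging of manual-curation decisions, and inheritance-mode-aware
    reporting of actionable-finding and carrier frequencies with per-gene
    allelic frequencies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
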