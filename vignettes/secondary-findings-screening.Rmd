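---
title: "Screening exome cohorts for medically actionable secondary findings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening exome cohorts for medically actionable secondary findings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfscreen)
library(dplyr)
```

## The problem

Diagnostic whole-exome sequencing can reveal disease-causing variants in
genes unrelated to the reason for testing. The ACMG recommends deliberately
screening a catalog of actionable loci — 81 genes in version 3.2, spanning
cancer-predisposition, cardiovascular, inborn-error-of-metabolism, and
miscellaneous phenotypes — and reporting pathogenic (PAT) or likely
pathogenic (L-PAT) variants found there. Estimating how often such
*secondary findings* occur in a population requires an anonymization-safe
cohort pipeline: per-individual genotypes must be reduced to aggregate
counts before any variant interpretation happens, which in turn constrains
what can be estimated (only observation counts, no per-person linkage).

`sfscreen` implements that pipeline end to end:

1. **Cohort resampling** (`apply_exclusions()`, `stratified_resample()`):
   one sample per family, one partner per consanguineous couple, no
   prenatal or foetal samples; then a census-stratified subsample so the
   cohort's geographic distribution tracks the general population.
2. **Genotype QC and aggregation** (`qc_pass()`, `merge_multisample()`,
   `aggregate_genotypes()`): calls below 10x read depth or genotype quality
   60 are discarded, single-sample VCFs are merged over the gene regions
   (exons plus 20 bp flanks), and only anonymized per-variant counts (AC,
   AN, AF, hom/het/hemi) leave this stage.
3. **Screening cascade** (`screen_variants()`, `apply_curation()`): a fixed
   priority order over annotation evidence — internal laboratory PAT/L-PAT
   assertions, then two-star ClinVar assertions (pathogenic includes,
   benign excludes), then a global allele-frequency cutoff of 0.5% with an
   exception list, then low-impact consequence terms — with everything left
   over routed to manual curation, whose verdicts are merged back in.
4. **Reporting** (`gene_summary()`, `cohort_frequencies()`): included
   variants are converted to actionable-finding and carrier estimates under
   each gene's inheritance mode and expressed as percentages of the cohort.

## The estimator and its conventions

Let $N$ be the cohort size and, for gene $g$ with included variants, let
$\mathrm{hom}_g$, $\mathrm{het}_g$, $\mathrm{hemi}_g$ be the summed
zygosity counts. The **actionable observations** are

- AD (dominant): $\mathrm{het}_g + \mathrm{hom}_g$;
- AR (recessive, di-allelic rule): $\mathrm{hom}_g$ only, while
  $\mathrm{het}_g$ is counted separately as **carriers**;
- XL (X-linked): $\mathrm{het}_g + \mathrm{hom}_g + \mathrm{hemi}_g$
  (heterozygous females count as findings).

The cohort-level frequency is $100 \times \sum_g a_g / N$, rounded half-up
to two decimals. Because the anonymized aggregates carry no per-person
linkage, these are *observation counts*: a person with two findings is
counted twice, so the estimator is an upper bound on the person-level
frequency; for the same reason compound heterozygotes in AR genes cannot
be detected and are not counted as di-allelic. The per-gene *allelic
frequency* column is $100 \times (\mathrm{hom}_g + \mathrm{het}_g +
\mathrm{hemi}_g) / (2N)$, rounded half-up to three decimals — the numerator
is the observation total, not the allele count, matching the reporting
convention of summary tables in this field. For X-linked genes the
denominator is $2N_f + N_m$ when the sex split is known, else $2N$ with a
warning.

All printed percentages use half-up (commercial) rounding
(`round_half_up()`), not R's default round-half-even, so they can be
re-derived exactly from the integer counts.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_depth`, `min_gq` | 10x, 60 | closed lower bounds for genotype QC |
| `flank_bp` | 20 bp | intronic flank added to each exon in the screening BED |
| `maf_cutoff` | 0.005 | closed exclusion bound on the gnomAD-style global AF |
| `exceptions` | HFE `NM_000410.4:c.845G>A` | variants screened despite a high MAF |
| `low_impact` | synonymous, intronic, UTR, intergenic, non-coding-exon terms | consequence terms excluded at the impact stage |
| `ploidy` | 2 | allelic-frequency denominator per person |

Design choices where the conventions were genuinely open, and how they
were resolved:

- **Rule precedence.** The cascade order is internal DB > ClinVar > MAF >
  impact. An internal classification *below* PAT/L-PAT does not
  short-circuit the cascade: an internal VUS with a two-star ClinVar
  pathogenic assertion is auto-included by the ClinVar rule. HGMD presence
  alone never auto-includes (it only defeats novelty).
- **"Two stars"** is interpreted as review status $\geq 2$ stars, since
  review-status ladders are ordinal.
- **QC-failing calls become missing**, reducing the called allele number
  AN, rather than being treated as reference — standard no-call semantics.
- **Apportionment** for stratified resampling uses the largest-remainder
  (Hamilton) method, which keeps every stratum within one sample of its
  proportional share; when a stratum's availability caps its target, the
  deficit is redistributed proportionally across unsaturated strata,
  iterated to a fixpoint. Ties in fractional remainders break by stratum
  order, making the plan deterministic. Sampling within strata is without
  replacement, so resampling a previous output with the same census and
  target is idempotent.
- **Retained family member / partner** under the exclusion rules is chosen
  uniformly at random under the seed; the rules themselves do not name a
  preference.
- **Variant identity** is the normalized (left-aligned, minimal) key
  `contig:pos:ref:alt`; multi-allelic records are split into biallelic keys
  before merging, and an indel's region membership is decided by its anchor
  base.

## What the synthetic cohort emulates — and what it does not

Real diagnostic NGS data cannot be redistributed, so the package ships a
generator (`sim_config()`, `plant_variants()`, `generate_cohort()`) that
emulates the *structure* the pipeline must survive: family clusters,
consanguineous couples, prenatal samples, a configurable male fraction
(default 0.5; real diagnostic cohorts rarely publish their sex split),
municipality assignment that may be deliberately discordant with the
census, genotypes drawn independently per individual at planted variants
with chosen het/hom frequencies, QC metrics placed just below the
thresholds (DP = 9 or GQ = 59) for a configurable fraction of calls, and
annotation records that steer each planted variant into a chosen branch of
the cascade. The truth set is tallied from the emitted genotypes, so every
downstream stage can be checked for exact agreement.

It does **not** emulate read-level error, linkage or haplotype structure,
Hardy–Weinberg coupling beyond the two stated zygosity probabilities,
realistic site-frequency spectra, or capture-kit coverage gaps. Passing
tests therefore demonstrate the pipeline's accounting and decision logic,
not robustness to upstream calling artefacts.

Genotypes are drawn independently per individual because the pipeline
operates entirely at the aggregate-count level; any within-family
correlation the generator could add would be removed by the one-per-family
exclusion rule before counting anyway.

## A small end-to-end run

Problem sizes throughout the examples and tests are deliberately modest —
cohorts of 60–2000 individuals with a handful of planted variants — which
is ample to pin down counting conventions that are exact by construction.

```{r pipeline}
catalog <- load_catalog()
planted <- plant_variants(
  gene = c("HFE", "LDLR", "GLA", "MUTYH"),
  truth_class = c("PAT", "PAT", "PAT", "L-PAT"),
  het_freq = c(0.10, 0.02, 0.02, 0.05),
  hom_freq = c(0.01, 0, 0.005, 0.002),
  annotation_profile = c("internal_db", "clinvar_2star_path",
                         "needs_curation", "internal_db"),
  novel = c(FALSE, FALSE, TRUE, FALSE),
  hgvs_c = c("NM_000410.4:c.845G>A", NA, NA, NA),
  catalog = catalog
)
cfg <- sim_config(
  n_samples = 500, seed = 42,
  municipalities = tibble::tibble(code = c("A", "B", "C"),
                                  population = c(100, 300, 600)),
  planted = planted
)
cohort <- generate_cohort(cfg, catalog)

bed <- build_bed(catalog, flank_bp = 20)
gt <- genotype_table(cohort$genotypes, bed, cohort$samples$sample_id)
agg <- aggregate_genotypes(gt, sex_map = cohort$samples[, c("sample_id", "sex")])

ann <- collate_annotations(generate_annotation_db(planted, seed = 42),
                           variants = planted)
decisions <- screen_variants(ann) |>
  apply_curation(tibble::tibble(hgvs_c = planted$hgvs_c[3],
                                curated_class = "PAT")) |>
  flag_novel()
funnel_summary(decisions)

report <- gene_summary(decisions, agg, catalog) |>
  cohort_frequencies(n = 500)
report
```

The same chain scales to a full cohort by replacing the generator output
with real single-sample VCFs (`merge_multisample()` reads them from disk)
and the mock annotation tables with exports from the laboratory's own
databases.

## Numerical and degenerate-input behaviour

- Empty inputs are legal everywhere: a cohort with no planted variants, a
  header-only VCF, an empty curation file, and an empty novel list all
  produce empty-but-well-formed outputs.
- Sites where every call fails QC have AN = 0 and are dropped with a
  notice rather than yielding NaN frequencies.
- Conflicting REF alleles at one site across input VCFs abort the merge:
  that always indicates an upstream normalization problem.
- Funnel stage counts partition the input by construction; the included
  total is their sum over the three include stages.
- The generator and both resampling steps restore the caller's RNG state,
  so seeded pipelines compose without surprising downstream draws.

## Known limitations

Observation counts double-count multi-finding individuals; compound
heterozygosity is invisible; X-linked allelic frequencies depend on a sex
split the aggregates may not carry; structural variants, repeat
expansions, and founder insertions that exome capture misses are out of
scope, as is the ACMG/AMP evidence-code engine itself — curation verdicts
enter as data, not as computed classifications.
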