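# sfscreen

Estimate the frequency of **medically actionable secondary findings** and of
**recessive-disease carriers** in an exome-sequenced cohort, screened against
the ACMG v3.2 catalog of 81 actionable genes.

Diagnostic exome data cannot leave the laboratory at the individual level,
so the pipeline is built around *anonymized aggregation*: per-individual
VCFs are QC-filtered (read depth ≥ 10×, genotype quality ≥ 60), restricted
to the catalog gene regions (exons + 20 bp flanks), and collapsed into
per-variant counts (AC, AN, AF, hom/het/hemi) before any interpretation
happens. Variants are then screened through a prioritized cascade —
internal laboratory PAT/L-PAT assertions, two-star ClinVar assertions
(pathogenic includes, benign excludes), a global allele-frequency cutoff of
0.5% with an exception list (the HFE `NM_000410.4:c.845G>A` variant stays
in), low-impact consequence terms — with the remainder resolved by manual
curation. Included variants become estimates under each gene's inheritance
mode:

- **AD**: actionable = het + hom observations;
- **AR** (di-allelic rule): actionable = hom; het observations are
  *carriers*, reported separately;
- **XL**: actionable = het + hom + hemi (heterozygous females count).

Cohort frequencies are `100 · Σ actionable / N` (half-up, 2 decimals);
per-gene allelic frequencies are `100 · (hom + het + hemi) / 2N` (half-up,
3 decimals). A census-stratified resampler (largest-remainder apportionment
with availability caps) turns a geography-biased diagnostic cohort into a
population-representative subset, and a synthetic-cohort generator with
planted variants and exact ground truth makes the whole pipeline testable
without access to protected data.

Intended users: genetics laboratories and registries estimating secondary-
finding burden from diagnostic exome collections, and anyone needing a
tested reference implementation of the screening conventions above.

## Worked example

A 500-person synthetic cohort with four planted variants (an HFE-like
common recessive pathogenic variant, a dominant LDLR variant asserted in
ClinVar, an X-linked GLA variant that needs curation, and a recessive
MUTYH variant):

```r
library(sfscreen)
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
cfg <- sim_config(n_samples = 500, seed = 42,
                  municipalities = tibble::tibble(code = c("A", "B", "C"),
                                                  population = c(100, 300, 600)),
                  planted = planted)
cohort <- generate_cohort(cfg, catalog)

gt  <- genotype_table(cohort$genotypes, build_bed(catalog),
                      cohort$samples$sample_id)
agg <- aggregate_genotypes(gt, sex_map = cohort$samples[, c("sample_id", "sex")])
ann <- collate_annotations(generate_annotation_db(planted, seed = 42),
                           variants = planted)
decisions <- screen_variants(ann) |>
  apply_curation(tibble::tibble(hgvs_c = planted$hgvs_c[3],
                                curated_class = "PAT")) |>
  flag_novel()

gene_summary(decisions, agg, catalog) |> cohort_frequencies(n = 500)
#> Secondary-findings cohort report (n = 500)
#>   actionable findings: 22 persons (4.40%)
#>   recessive carriers:  70 persons (14.00%)
#>   by phenotype group:
#>     cancer              1 actionable (4.55% of actionable, 0.20% of cohort)
#>     cardiovascular      5 actionable (22.73% of actionable, 1.00% of cohort)
#>     metabolic          12 actionable (54.55% of actionable, 2.40% of cohort)
#>     miscellaneous       4 actionable (18.18% of actionable, 0.80% of cohort)
```

Reading: 22 variant observations in this cohort warrant clinical reporting
(4.40% of 500 persons) — here dominated by the X-linked GLA variant
(metabolic group) and the dominant LDLR variant (cardiovascular) — while 70
persons are heterozygous carriers for the two recessive genes (HFE, MUTYH)
and would be reported only in a carrier-screening context. Because the
aggregates are anonymized, these are observation counts: a person with two
findings is counted twice (an upper-bound estimator). `tidy()`, `glance()`
and `autoplot()` work on the report object; `render_table1()` and
`render_novel_table()` produce the per-gene and novel-variant tables.

See the vignette (`vignettes/secondary-findings-screening.Rmd`) for the
model, conventions and design decisions in full.

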