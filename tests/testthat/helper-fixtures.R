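# Shared fixtures: everything is built in code at test time.

toy_municipalities <- function() {
  tibble::tibble(code = c("A", "B", "C"), population = c(100, 300, 600))
}

# A planted-variant set that exercises every branch of the screening cascade.
default_planted <- function(catalog = load_catalog()) {
  plant_variants(
    gene = c("HFE", "LDLR", "GLA", "MUTYH", "BRCA2", "TTN", "MYH7", "RYR1"),
    truth_class = c("PAT", "PAT", "PAT", "L-PAT", "BEN", "VUS", "VUS", "VUS"),
    het_freq = c(0.10, 0.02, 0.02, 0.05, 0.10, 0.01, 0.02, 0.03),
    hom_freq = c(0.01, 0, 0.005, 0.002, 0.01, 0, 0, 0),
    annotation_profile = c("internal_db", "clinvar_2star_path", "needs_curation",
                           "internal_db", "clinvar_2star_benign", "high_maf",
                           "low_impact", "needs_curation"),
    novel = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    hgvs_c = c("NM_000410.4:c.845G>A", rep(NA_character_, 7)),
    catalog = catalog
  )
}

small_cohort <- function(n = 60, seed = 1, planted = NULL,
                         catalog = load_catalog(), qc_noise = 0.05, ...) {
  planted <- planted %||% default_planted(catalog)
  cfg <- sim_config(n_samples = n, seed = seed,
                    municipalities = toy_municipalities(),
                    planted = planted, qc_noise = qc_noise, ...)
  generate_cohort(cfg, catalog)
}

# Minimal hand-built catalog for interval-logic tests: one or two genes with
# explicit exon lists on one contig.
toy_catalog <- function(exons = list(GENE1 = list(start = c(101L, 231L),
                                                  end = c(200L, 300L)))) {
  tibble::tibble(
    symbol = names(exons),
    phenotype_group = "cancer",
    disease = "toy disease",
    inheritance = "AD",
    transcript = paste0("SYN-", names(exons), "-201"),
    contig = "1",
    exon_start = lapply(exons, `[[`, "start"),
    exon_end = lapply(exons, `[[`, "end")
  )
}

# Annotation record with every evidence field, defaulting to "no evidence".
ann_record <- function(contig = "1", pos = 100L, ref = "A", alt = "G",
                       internal_class = NA_character_,
                       clinvar_class = NA_character_, clinvar_stars = NA_integer_,
                       in_hgmd = FALSE, gnomad_af_global = NA_real_,
                       impact_term = "missense_variant", hgvs_c = NA_character_,
                       hgvs_p = NA_character_, clinvar_id = NA_character_) {
  tibble::tibble(contig = contig, pos = pos, ref = ref, alt = alt,
                 internal_class = internal_class, clinvar_class = clinvar_class,
                 clinvar_stars = clinvar_stars, in_hgmd = in_hgmd,
                 gnomad_af_global = gnomad_af_global, impact_term = impact_term,
                 hgvs_c = hgvs_c, hgvs_p = hgvs_p, clinvar_id = clinvar_id)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
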