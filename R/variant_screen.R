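#' Default MAF exception list
#'
#' Variants exempt from the population allele-frequency exclusion. The
#' default contains the common hereditary-haemochromatosis HFE variant
#' NM_000410.4:c.845G>A (p.Cys282Tyr), which is screened despite its high
#' population frequency. Entries match either a variant's cDNA HGVS string
#' or its `"contig:pos:ref:alt"` id.
#'
#' @return Character vector of identifiers.
#' @export
maf_exceptions <- function() {
  "NM_000410.4:c.845G>A"
}

#' Default low-impact Sequence Ontology terms
#'
#' Molecular-consequence terms excluded at the impact stage of the cascade.
#' Unknown terms are treated as not-low (conservative retention).
#'
#' @return Character vector of terms.
#' @export
low_impact_terms <- function() {
  c("synonymous_variant", "intron_variant", "5_prime_UTR_variant",
    "3_prime_UTR_variant", "intergenic_variant", "non_coding_transcript_exon_variant")
}

#' Collate annotation tables into one record per variant
#'
#' Joins the internal-database, ClinVar, HGMD, gnomAD, and impact tables
#' (as produced by [generate_annotation_db()] or read from TSVs) into a wide
#' annotation tibble keyed by variant, with absent evidence as NA.
#'
#' @param annotations Named list of tibbles `internal`, `clinvar`, `hgmd`,
#'   `gnomad`, `impact`, each keyed by `contig`, `pos`, `ref`, `alt`.
#' @param variants Optional tibble of variant keys to annotate (defaults to
#'   the union of keys across the tables).
#' @return Tibble with columns `contig`, `pos`, `ref`, `alt`,
#'   `internal_class`, `clinvar_class`, `clinvar_stars`, `clinvar_id`,
#'   `in_hgmd`, `gnomad_af_global`, `impact_term`, `hgvs_c`, `hgvs_p`.
#' @export
collate_annotations <- function(annotations, variants = NULL) {
  key_cols <- c("contig", "pos", "ref", "alt")
  if (is.null(variants)) {
    variants <- purrr::map(annotations, ~ .x %>% select(dplyr::all_of(key_cols))) %>%
      bind_rows() %>%
      distinct()
  } else {
    variants <- variants %>% select(dplyr::all_of(key_cols)) %>% distinct()
  }
  out <- variants %>%
    left_join(annotations$internal, by = key_cols) %>%
    left_join(annotations$clinvar, by = key_cols) %>%
    left_join(annotations$hgmd, by = key_cols) %>%
    left_join(annotations$gnomad, by = key_cols) %>%
    left_join(annotations$impact, by = key_cols)
  for (col in c("internal_class", "clinvar_class", "hgvs_c", "hgvs_p")) {
    if (!col %in% names(out)) out[[col]] <- NA_character_
  }
  if (!"clinvar_stars" %in% names(out)) out$clinvar_stars <- NA_integer_
  if (!"clinvar_id" %in% names(out)) out$clinvar_id <- NA_character_
  if (!"gnomad_af_global" %in% names(out)) out$gnomad_af_global <- NA_real_
  if (!"impact_term" %in% names(out)) out$impact_term <- NA_character_
  out$in_hgmd <- tidyr::replace_na(out[["in_hgmd"]] %||% FALSE, FALSE)
  bad <- !is.na(out$clinvar_class) & is.na(out$clinvar_stars)
  if (any(bad)) abort("clinvar_stars must be present whenever clinvar_class is")
  out
}

#' Screen annotated variants through the prioritized cascade
#'
#' Applies the filtering cascade in fixed priority order; the first matching
#' rule decides each variant's stage:
#' 1. internal laboratory class PAT/L-PAT — automatically included;
#' 2. ClinVar PAT/L-PAT with >= 2 review stars — automatically included;
#' 3. ClinVar BEN/L-BEN with >= 2 review stars — excluded;
#' 4. global allele frequency >= `maf_cutoff` (default 0.5%) and not on the
#'    exception list — excluded;
#' 5. low-impact molecular consequence — excluded;
#' 6. otherwise — needs manual curation.
#'
#' An internal classification below PAT/L-PAT does not block rule 2: the
#' internal database only short-circuits the cascade when it asserts
#' pathogenicity.
#'
#' @param annotations Wide annotation tibble from [collate_annotations()].
#' @param maf_cutoff Closed exclusion bound on the global allele frequency.
#' @param exceptions Identifiers exempt from the MAF rule (see
#'   [maf_exceptions()]).
#' @param low_impact Character vector of low-impact terms (see
#'   [low_impact_terms()]).
#' @return Decisions tibble: key columns, `stage`, `final_class` (set for
#'   included variants), `included`, plus the annotation evidence carried
#'   through.
#' @examples
#' ann <- tibble::tibble(
#'   contig = "1", pos = 100L, ref = "A", alt = "G",
#'   internal_class = "PAT", clinvar_class = NA, clinvar_stars = NA_integer_,
#'   in_hgmd = FALSE, gnomad_af_global = 0.02, impact_term = "missense_variant",
#'   hgvs_c = NA, hgvs_p = NA, clinvar_id = NA
#' )
#' screen_variants(ann)$stage # internal assertion outranks the MAF rule
#' @export
screen_variants <- function(annotations, maf_cutoff = 0.005,
                            exceptions = maf_exceptions(),
                            low_impact = low_impact_terms()) {
  ann <- annotations
  vid <- variant_id(ann$contig, ann$pos, ann$ref, ann$alt)
  excepted <- vid %in% exceptions |
    (!is.na(ann$hgvs_c) & ann$hgvs_c %in% exceptions)
  path_class <- c("PAT", "L-PAT")
  ben_class <- c("BEN", "L-BEN")
  stage <- dplyr::case_when(
    !is.na(ann$internal_class) & ann$internal_class %in% path_class ~ "auto_include_internal",
    !is.na(ann$clinvar_class) & ann$clinvar_class %in% path_class &
      ann$clinvar_stars >= 2L ~ "auto_include_clinvar",
    !is.na(ann$clinvar_class) & ann$clinvar_class %in% ben_class &
      ann$clinvar_stars >= 2L ~ "exclude_benign_clinvar",
    !is.na(ann$gnomad_af_global) & ann$gnomad_af_global >= maf_cutoff &
      !excepted ~ "exclude_maf",
    !is.na(ann$impact_term) & ann$impact_term %in% low_impact ~ "exclude_low_impact",
    TRUE ~ "needs_curation"
  )
  final_class <- dplyr::case_when(
    stage == "auto_include_internal" ~ ann$internal_class,
    stage == "auto_include_clinvar" ~ ann$clinvar_class,
    TRUE ~ NA_character_
  )
  ann %>%
    mutate(stage = stage, final_class = final_class,
           included = stage %in% INCLUDED_STAGES)
}

#' Merge manual-curation decisions into screening decisions
#'
#' Variants at the `needs_curation` stage are resolved by the curation file:
#' curated PAT/L-PAT becomes `curated_include`; any other curated class
#' becomes `curated_exclude`. Variants absent from the file become
#' `curated_exclude` by default, or remain `needs_curation` (reported as
#' pending) when `absent_pending = TRUE`. Curation entries for variants not
#' at the curation stage are rejected; entries for unscreened variants are
#' ignored with a warning.
#'
#' @param decisions Decisions from [screen_variants()].
#' @param curation Tibble with key columns (`contig`, `pos`, `ref`, `alt`,
#'   or an `hgvs_c` column) and `curated_class`.
#' @param absent_pending Keep uncurated variants pending instead of
#'   excluding them.
#' @return Updated decisions tibble.
#' @export
apply_curation <- function(decisions, curation, absent_pending = FALSE) {
  dec <- decisions
  vid <- variant_id(dec$contig, dec$pos, dec$ref, dec$alt)
  if (all(c("contig", "pos", "ref", "alt") %in% names(curation))) {
    cid <- variant_id(curation$contig, curation$pos, curation$ref, curation$alt)
    did <- vid
  } else if ("hgvs_c" %in% names(curation)) {
    cid <- curation$hgvs_c
    did <- dec$hgvs_c
  } else {
    abort("curation table needs either variant key columns or hgvs_c")
  }
  if (anyDuplicated(cid)) abort("duplicate keys in curation table")
  if (any(!curation$curated_class %in% CLASS_LEVELS)) abort("invalid curated_class")
  hit <- match(cid, did)
  if (any(is.na(hit))) {
    warn(paste0(sum(is.na(hit)), " curation entr(ies) for unscreened variants ignored"))
    curation <- curation[!is.na(hit), ]
    cid <- cid[!is.na(hit)]
    hit <- hit[!is.na(hit)]
  }
  not_pending <- dec$stage[hit] != "needs_curation"
  if (any(not_pending)) {
    abort(paste0("curation entries target variants not at needs_curation: ",
                 paste(head(cid[not_pending], 3), collapse = ", ")))
  }
  curated_class <- rep(NA_character_, nrow(dec))
  curated_class[hit] <- curation$curated_class
  pending <- dec$stage == "needs_curation"
  dec %>%
    mutate(
      stage = dplyr::case_when(
        pending & curated_class %in% c("PAT", "L-PAT") ~ "curated_include",
        pending & !is.na(curated_class) ~ "curated_exclude",
        pending & is.na(curated_class) & !absent_pending ~ "curated_exclude",
        TRUE ~ .data$stage
      ),
      final_class = if_else(.data$stage == "curated_include", curated_class,
                            .data$final_class),
      included = .data$stage %in% INCLUDED_STAGES
    )
}

#' Funnel summary of screening decisions
#'
#' Counts variants at every terminal stage of the cascade (stages with no
#' variants appear with zero counts, so the counts always partition the
#' input) and totals the included variants.
#'
#' @param decisions Decisions tibble.
#' @return Tibble `stage`, `n`, ordered by cascade stage, with attributes
#'   `included_total` and `n_screened`.
#' @export
funnel_summary <- function(decisions) {
  counts <- decisions %>% count(.data$stage)
  out <- tibble(stage = SCREEN_STAGES) %>%
    left_join(counts, by = "stage") %>%
    mutate(n = tidyr::replace_na(.data$n, 0L))
  structure(out,
            included_total = sum(out$n[out$stage %in% INCLUDED_STAGES]),
            n_screened = nrow(decisions))
}

#' Flag novel included variants
#'
#' An included variant is novel when no ClinVar assertion exists for it and
#' it is absent from HGMD — i.e., it has not been previously reported.
#'
#' @param decisions Decisions tibble (annotation evidence columns present).
#' @return The tibble with a logical `novel` column (`NA` for non-included
#'   variants).
#' @export
flag_novel <- function(decisions) {
  decisions %>%
    mutate(novel = if_else(.data$included,
                           is.na(.data$clinvar_class) & !.data$in_hgmd,
                           NA))
}

#' Novelty summary of included variants
#'
#' @param decisions Decisions tibble after [flag_novel()].
#' @return One-row tibble: `n_included`, `n_novel`, `novel_pct` (half-up,
#'   whole percent).
#' @export
novel_summary <- function(decisions) {
  if (!"novel" %in% names(decisions)) decisions <- flag_novel(decisions)
  inc <- decisions %>% filter(.data$included)
  tibble(
    n_included = nrow(inc),
    n_novel = sum(inc$novel),
    novel_pct = round_half_up(100 * sum(inc$novel) / max(nrow(inc), 1L), 0)
  )
}

#' Funnel bar chart
#'
#' @param decisions Decisions tibble.
#' @return A ggplot object showing variant counts per cascade stage.
#' @export
plot_funnel <- function(decisions) {
  fs <- funnel_summary(decisions) %>%
    mutate(stage = factor(.data$stage, levels = rev(SCREEN_STAGES)),
           outcome = if_else(as.character(.data$stage) %in% INCLUDED_STAGES,
                             "included", "excluded/pending"))
  ggplot2::ggplot(fs, ggplot2::aes(x = .data$n, y = .data$stage, fill = .data$outcome)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "variants", y = NULL, fill = NULL,
                  title = "Screening cascade funnel") +
    ggplot2::theme_minimal()
}
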