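#' Actionable and carrier observations for one gene
#'
#' Converts zygosity counts of included PAT/L-PAT variants into actionable
#' and carrier observation counts under the gene's inheritance mode.
#' Dominant (AD) genes: every het or hom observation is actionable. X-linked
#' (XL) genes: het, hom, and hemizygous observations are all actionable
#' (heterozygous females count). Recessive (AR) genes follow the di-allelic
#' rule: only homozygotes are actionable; heterozygotes are carriers.
#' Compound heterozygotes cannot be detected without per-person genotypes
#' and are not counted.
#'
#' @param inheritance "AD", "AR", or "XL" (vectorized).
#' @param n_het,n_hom,n_hemi Observation counts over the gene's included
#'   variants.
#' @return Tibble with `actionable_obs` and `carrier_obs`.
#' @examples
#' classify_gene("AR", n_het = 207, n_hom = 4) # 4 actionable, 207 carriers
#' @export
classify_gene <- function(inheritance, n_het = 0L, n_hom = 0L, n_hemi = 0L) {
  bad <- setdiff(unique(inheritance), c("AD", "AR", "XL"))
  if (length(bad)) abort(paste0("unknown inheritance mode: ", paste(bad, collapse = ", ")))
  k <- max(length(inheritance), length(n_het), length(n_hom), length(n_hemi))
  n_het <- rep_len(as.integer(n_het), k)
  n_hom <- rep_len(as.integer(n_hom), k)
  n_hemi <- rep_len(as.integer(n_hemi), k)
  inheritance <- rep_len(inheritance, k)
  tibble(
    actionable_obs = dplyr::case_when(
      inheritance == "AD" ~ n_het + n_hom,
      inheritance == "AR" ~ n_hom,
      inheritance == "XL" ~ n_het + n_hom + n_hemi
    ),
    carrier_obs = if_else(inheritance == "AR", n_het, 0L)
  )
}

#' Allelic frequency as a percentage
#'
#' The reporting convention for per-gene allelic frequencies: the number of
#' variant observations over the total number of chromosomes in the cohort,
#' `100 * table_total / (ploidy * n)`, rounded half-up to three decimals.
#'
#' @param table_total Total variant observations (hom + het + hemi) for the
#'   gene.
#' @param n Cohort size (persons).
#' @param ploidy Chromosomes per person at the locus (2 for autosomes).
#' @return Percentage rounded half-up to 3 decimals.
#' @examples
#' allelic_frequency_pct(211, 3972) # 2.656
#' @export
allelic_frequency_pct <- function(table_total, n, ploidy = 2) {
  stopifnot(all(n > 0))
  round_half_up(100 * table_total / (ploidy * n), 3)
}

#' Per-gene summaries of included variants
#'
#' Joins screening decisions to aggregate counts and rolls them up per
#' catalog gene. Every catalog gene appears (zero rows for genes with no
#' included findings). The allelic-frequency denominator is `2n` for
#' autosomal genes; for X-linked genes it is `2*n_female + n_male` when sex
#' counts are available, else `2n` with a warning.
#'
#' @param decisions Decisions tibble from [screen_variants()] /
#'   [apply_curation()].
#' @param aggregates Aggregate counts from [aggregate_genotypes()] (carrying
#'   a `gene` column).
#' @param catalog Catalog from [load_catalog()].
#' @param n Cohort size. Defaults to the `n_samples` attribute of
#'   `aggregates`.
#' @param n_female,n_male Optional sex split for the X-linked denominator;
#'   default from `aggregates` attributes.
#' @return Tibble with one row per gene: `gene`, `phenotype_group`,
#'   `disease`, `inheritance`, `n_variants`, `table_total`, `n_hom`,
#'   `n_het`, `n_hemi`, `allelic_freq_pct`, `actionable_obs`, `carrier_obs`.
#' @export
gene_summary <- function(decisions, aggregates, catalog, n = NULL,
                         n_female = NULL, n_male = NULL) {
  n <- n %||% attr(aggregates, "n_samples")
  if (is.null(n)) abort("cohort size n is required")
  n_female <- n_female %||% attr(aggregates, "n_female")
  n_male <- n_male %||% attr(aggregates, "n_male")
  key_cols <- c("contig", "pos", "ref", "alt")
  included <- decisions %>%
    filter(.data$included) %>%
    select(dplyr::all_of(key_cols))
  counts <- as_tibble(aggregates) %>%
    semi_join(included, by = key_cols) %>%
    group_by(gene = .data$gene) %>%
    summarise(
      n_variants = n(),
      table_total = sum(.data$table_total),
      n_hom = sum(.data$n_hom),
      n_het = sum(.data$n_het),
      n_hemi = sum(.data$n_hemi),
      .groups = "drop"
    )
  out <- catalog %>%
    select(gene = "symbol", "phenotype_group", "disease", "inheritance") %>%
    left_join(counts, by = "gene") %>%
    mutate(across(c("n_variants", "table_total", "n_hom", "n_het", "n_hemi"),
                  ~ tidyr::replace_na(.x, 0L)))
  xl <- out$inheritance == "XL"
  denom <- rep(2 * n, nrow(out))
  if (any(xl)) {
    if (!is.null(n_female) && !is.null(n_male)) {
      denom[xl] <- 2 * n_female + n_male
    } else {
      warn("sex split unavailable; using 2n as the X-linked allelic-frequency denominator")
    }
  }
  out %>%
    mutate(
      allelic_freq_pct = round_half_up(100 * .data$table_total / denom, 3),
      classify_gene(.data$inheritance, .data$n_het, .data$n_hom, .data$n_hemi)
    )
}

#' Cohort-level actionable-finding and carrier frequencies
#'
#' Sums actionable and carrier observations over genes and expresses them as
#' percentages of the cohort, with per-phenotype-group and per-disease
#' breakdowns. Person counts are observation counts: individual-level
#' linkage is removed before aggregation, so one person carrying two
#' findings is counted twice — an upper-bound estimator. Percentages are
#' rounded half-up to two decimals.
#'
#' @param gene_results Tibble with `actionable_obs` and `carrier_obs`
#'   columns, and optionally `phenotype_group`, `disease`, `gene` for the
#'   breakdowns (e.g. from [gene_summary()]).
#' @param n Cohort size (> 0).
#' @return A `cohort_report` object: list with `n`, `actionable_persons`,
#'   `actionable_pct`, `carrier_persons`, `carrier_pct`, `by_group`,
#'   `by_disease`, `by_gene` (tibbles; NULL when the grouping column is
#'   absent). Supports `tidy()`, `glance()`, `autoplot()`, and `print()`.
#' @examples
#' gr <- tibble::tibble(
#'   phenotype_group = c("cardiovascular", "cancer", "metabolic", "miscellaneous"),
#'   actionable_obs = c(120L, 80L, 4L, 42L), carrier_obs = 0L
#' )
#' cohort_frequencies(gr, n = 3972)
#' @export
cohort_frequencies <- function(gene_results, n) {
  if (length(n) != 1 || n <= 0) abort("cohort size n must be a single positive number")
  stopifnot(all(c("actionable_obs", "carrier_obs") %in% names(gene_results)))
  actionable <- sum(gene_results$actionable_obs)
  carriers <- sum(gene_results$carrier_obs)
  breakdown <- function(col) {
    if (!col %in% names(gene_results)) return(NULL)
    gene_results %>%
      group_by(dplyr::across(dplyr::all_of(col))) %>%
      summarise(
        actionable_obs = sum(.data$actionable_obs),
        carrier_obs = sum(.data$carrier_obs),
        .groups = "drop"
      ) %>%
      mutate(
        pct_of_actionable = round_half_up(100 * .data$actionable_obs / max(actionable, 1L), 2),
        pct_of_cohort = round_half_up(100 * .data$actionable_obs / n, 2),
        carrier_pct_of_cohort = round_half_up(100 * .data$carrier_obs / n, 2)
      )
  }
  structure(
    list(
      n = n,
      actionable_persons = actionable,
      actionable_pct = round_half_up(100 * actionable / n, 2),
      carrier_persons = carriers,
      carrier_pct = round_half_up(100 * carriers / n, 2),
      by_group = breakdown("phenotype_group"),
      by_disease = breakdown("disease"),
      by_gene = breakdown("gene")
    ),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Secondary-findings cohort report (n = ", x$n, ")\n", sep = "")
  cat("  actionable findings: ", x$actionable_persons, " persons (",
      format(x$actionable_pct, nsmall = 2), "%)\n", sep = "")
  cat("  recessive carriers:  ", x$carrier_persons, " persons (",
      format(x$carrier_pct, nsmall = 2), "%)\n", sep = "")
  if (!is.null(x$by_group)) {
    cat("  by phenotype group:\n")
    g <- x$by_group
    for (i in seq_len(nrow(g))) {
      cat(sprintf("    %-16s %4d actionable (%.2f%% of actionable, %.2f%% of cohort)\n",
                  g$phenotype_group[i], g$actionable_obs[i],
                  g$pct_of_actionable[i], g$pct_of_cohort[i]))
    }
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cohort_report <- function(x, ...) {
  x$by_group %||%
    tibble(phenotype_group = character(), actionable_obs = integer(),
           carrier_obs = integer(), pct_of_actionable = numeric(),
           pct_of_cohort = numeric(), carrier_pct_of_cohort = numeric())
}

#' @exportS3Method generics::glance
glance.cohort_report <- function(x, ...) {
  tibble(
    n = x$n,
    actionable_persons = x$actionable_persons,
    actionable_pct = x$actionable_pct,
    carrier_persons = x$carrier_persons,
    carrier_pct = x$carrier_pct
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.cohort_report <- function(object, ...) {
  df <- tidy(object) %>%
    tidyr::pivot_longer(c("actionable_obs", "carrier_obs"),
                        names_to = "kind", values_to = "persons") %>%
    mutate(kind = if_else(.data$kind == "actionable_obs", "actionable", "carrier"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phenotype_group, y = .data$persons,
                                   fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "persons", fill = NULL,
                  title = "Actionable findings and carriers by phenotype group") +
    ggplot2::theme_minimal()
}

#' Render the per-gene summary table
#'
#' The tabular report of findings per gene: ordered by phenotype group then
#' disease, all catalog genes present with zero rows where nothing was
#' included.
#'
#' @param gene_summaries Output of [gene_summary()].
#' @return Tibble with columns `phenotype_group`, `disease`, `gene`,
#'   `inheritance`, `n_variants`, `total`, `hom`, `het`, `hemi`,
#'   `allelic_freq_pct`.
#' @export
render_table1 <- function(gene_summaries) {
  gene_summaries %>%
    arrange(.data$phenotype_group, .data$disease, .data$gene) %>%
    select("phenotype_group", "disease", "gene", "inheritance", "n_variants",
           total = "table_total", hom = "n_hom", het = "n_het", hemi = "n_hemi",
           "allelic_freq_pct")
}

#' Render the novel-variant table
#'
#' One row per novel included variant: gene, cDNA HGVS, predicted splicing
#' impact (Y/N, from the consequence term), protein change, gnomAD global
#' frequency (%), and ClinVar id (blank when absent).
#'
#' @param decisions Decisions tibble after [flag_novel()], carrying
#'   annotation evidence columns.
#' @param gene_map Optional tibble mapping variant keys to `gene` (e.g. the
#'   aggregate table); if the decisions already have a `gene` column it is
#'   used directly.
#' @return Tibble `gene`, `hgvs_c`, `splicing`, `hgvs_p`, `gnomad_freq_pct`,
#'   `clinvar_id`.
#' @export
render_novel_table <- function(decisions, gene_map = NULL) {
  if (!"novel" %in% names(decisions)) decisions <- flag_novel(decisions)
  dec <- decisions %>% filter(.data$included, .data$novel)
  if (!"gene" %in% names(dec) && !is.null(gene_map)) {
    dec <- dec %>%
      left_join(as_tibble(gene_map) %>% select("contig", "pos", "ref", "alt", "gene"),
                by = c("contig", "pos", "ref", "alt"))
  }
  if (!"gene" %in% names(dec)) dec$gene <- NA_character_
  dec %>%
    mutate(
      splicing = if_else(stringr::str_detect(tidyr::replace_na(.data$impact_term, ""),
                                             "splice"), "Y", "N"),
      gnomad_freq_pct = if_else(is.na(.data$gnomad_af_global), NA_real_,
                                round_half_up(100 * .data$gnomad_af_global, 4))
    ) %>%
    select("gene", "hgvs_c", "splicing", "hgvs_p", "gnomad_freq_pct", "clinvar_id") %>%
    arrange(.data$gene, .data$hgvs_c)
}
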