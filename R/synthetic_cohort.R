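#' Configuration for a synthetic screening cohort
#'
#' Bundles and validates all parameters of the synthetic-cohort generator.
#' The generator emulates a diagnostic exome cohort: family clusters,
#' consanguineous couples, prenatal/foetal samples, municipality assignment
#' (possibly discordant with the census), per-genotype QC metrics around the
#' read-depth/genotype-quality thresholds, and planted variants whose
#' annotation profile steers them into a chosen branch of the screening
#' cascade.
#'
#' @param n_samples Number of individuals (>= 1).
#' @param seed Integer seed; the whole cohort is deterministic given the
#'   config (including the seed).
#' @param municipalities Tibble with columns `code` and `population`
#'   (positive census population per municipality).
#' @param planted Tibble of planted variants from [plant_variants()]; may
#'   have zero rows.
#' @param family_rate Probability a sample joins an existing family.
#' @param consanguinity_rate Probability a sample is linked as the partner of
#'   an earlier, unpartnered sample.
#' @param prenatal_rate Probability a sample is of prenatal or foetal type.
#' @param male_fraction Probability a sample is male (supports hemizygous
#'   X-linked genotypes).
#' @param qc_noise Fraction of emitted variant calls given a failing QC
#'   metric (DP = 9 or GQ = 59, just below the default thresholds).
#' @param municipality_weights Optional sampling weights over municipalities
#'   for the cohort (defaults to census proportions); lets the cohort be
#'   deliberately geography-skewed relative to the census.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_samples, seed, municipalities,
                       planted = plant_variants(),
                       family_rate = 0.05, consanguinity_rate = 0.02,
                       prenatal_rate = 0.05, male_fraction = 0.5,
                       qc_noise = 0.02, municipality_weights = NULL) {
  probs <- c(family_rate, consanguinity_rate, prenatal_rate, male_fraction, qc_noise)
  if (any(probs < 0 | probs > 1)) abort("all rate parameters must lie in [0, 1]")
  if (n_samples < 1) abort("n_samples must be >= 1")
  stopifnot(all(c("code", "population") %in% names(municipalities)))
  if (any(municipalities$population <= 0)) abort("municipality populations must be > 0")
  if (anyDuplicated(municipalities$code)) abort("duplicate municipality codes")
  w <- municipality_weights %||% (municipalities$population / sum(municipalities$population))
  if (length(w) != nrow(municipalities)) abort("municipality_weights length mismatch")
  structure(
    list(
      n_samples = as.integer(n_samples), seed = as.integer(seed),
      municipalities = as_tibble(municipalities), planted = planted,
      family_rate = family_rate, consanguinity_rate = consanguinity_rate,
      prenatal_rate = prenatal_rate, male_fraction = male_fraction,
      qc_noise = qc_noise, municipality_weights = w
    ),
    class = "sim_config"
  )
}

#' Describe variants to plant in a synthetic cohort
#'
#' Each planted variant carries its genomic key, true five-tier
#' classification, per-individual zygosity frequencies, and an
#' `annotation_profile` naming the branch of the screening cascade its
#' generated annotation should trigger:
#' `internal_db` (internal laboratory PAT/L-PAT assertion),
#' `clinvar_2star_path` / `clinvar_2star_benign` (two-star ClinVar
#' assertions), `high_maf` (population allele frequency at or above the
#' exclusion cutoff), `low_impact` (low-consequence Sequence Ontology term),
#' or `needs_curation` (no automatic evidence; falls through to manual
#' review).
#'
#' @param gene Gene symbols (must exist in `catalog`).
#' @param truth_class True classification, one of PAT, L-PAT, VUS, L-BEN, BEN.
#' @param het_freq,hom_freq Per-individual probabilities of a heterozygous /
#'   homozygous genotype (`het_freq + hom_freq <= 1`). On the X chromosome,
#'   males are hemizygous for the alternate allele with probability
#'   `het_freq + hom_freq`.
#' @param annotation_profile Cascade branch to exercise (see above).
#' @param novel Whether the variant is absent from the ClinVar/HGMD mocks.
#' @param hgvs_c Optional cDNA HGVS string (defaults to a synthetic one);
#'   useful for planting variants on a MAF exception list.
#' @param exon_index Which exon of the gene hosts the variant.
#' @param offset Offset of the variant within that exon.
#' @param catalog Catalog from [load_catalog()] used to place the variant.
#' @return Tibble of planted variants (zero rows when called without genes).
#' @export
plant_variants <- function(gene = character(), truth_class = character(),
                           het_freq = numeric(), hom_freq = 0,
                           annotation_profile = character(), novel = FALSE,
                           hgvs_c = NA_character_, exon_index = 1L, offset = NULL,
                           catalog = load_catalog()) {
  if (length(gene) == 0) {
    return(tibble(
      contig = character(), pos = integer(), ref = character(), alt = character(),
      gene = character(), truth_class = character(), het_freq = numeric(),
      hom_freq = numeric(), annotation_profile = character(), novel = logical(),
      hgvs_c = character()
    ))
  }
  bad <- setdiff(gene, catalog$symbol)
  if (length(bad)) {
    abort(paste0("planted variant outside any catalog gene: ", paste(bad, collapse = ", ")))
  }
  pv <- tibble(
    gene = gene, truth_class = truth_class, het_freq = het_freq,
    hom_freq = hom_freq, annotation_profile = annotation_profile,
    novel = novel, hgvs_c = hgvs_c, exon_index = as.integer(exon_index)
  )
  if (any(!pv$truth_class %in% CLASS_LEVELS)) abort("invalid truth_class")
  if (any(pv$het_freq + pv$hom_freq > 1)) abort("het_freq + hom_freq must be <= 1")
  idx <- match(pv$gene, catalog$symbol)
  pv$contig <- catalog$contig[idx]
  # place each variant a distinct distance into its chosen exon so that two
  # variants planted in the same gene never collide
  off <- offset %||% (10L + 3L * (seq_len(nrow(pv)) - 1L))
  starts <- purrr::map2_int(idx, pv$exon_index, ~ catalog$exon_start[[.x]][.y])
  ends <- purrr::map2_int(idx, pv$exon_index, ~ catalog$exon_end[[.x]][.y])
  pv$pos <- as.integer(starts + off)
  if (any(pv$pos > ends)) abort("planted variant offset falls outside its exon")
  bases <- c("A", "C", "G", "T")
  pv$ref <- bases[(pv$pos %% 4L) + 1L]
  pv$alt <- bases[((pv$pos + 1L) %% 4L) + 1L]
  pv$hgvs_c <- ifelse(
    is.na(pv$hgvs_c),
    paste0(catalog$transcript[idx], ":c.", off, pv$ref, ">", pv$alt),
    pv$hgvs_c
  )
  pv %>%
    select("contig", "pos", "ref", "alt", "gene", "truth_class", "het_freq",
           "hom_freq", "annotation_profile", "novel", "hgvs_c")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws `n_samples` individuals with family/couple/prenatal structure,
#' municipality and sex assignment, and genotypes at each planted variant
#' (independently per individual, with the configured heterozygote and
#' homozygote probabilities; males are hemizygous on the X). A fraction
#' `qc_noise` of the emitted variant calls receives a failing QC metric.
#' The returned truth set is tallied directly from the emitted genotypes,
#' so downstream stages can be checked against it exactly.
#'
#' @param config A [sim_config()].
#' @param catalog Catalog from [load_catalog()] (used to validate placement
#'   and to decide X-linked hemizygosity).
#' @return A list of class `sim_cohort` with elements `samples` (metadata
#'   tibble: `sample_id`, `family_id`, `partner_id`, `municipality`,
#'   `sample_type`, `sex`), `genotypes` (long tibble of non-reference calls:
#'   key columns, `sample_id`, `zygosity`, `dp`, `gq`), `planted`, and
#'   `truth` (list with `variants` — expected post-QC aggregate counts and
#'   expected screening stage per planted variant — and `n_samples`).
#' @examples
#' cfg <- sim_config(
#'   n_samples = 50, seed = 1,
#'   municipalities = tibble::tibble(code = c("A", "B"), population = c(100, 300)),
#'   planted = plant_variants("HFE", "PAT", het_freq = 0.1, hom_freq = 0.01,
#'     annotation_profile = "internal_db")
#' )
#' cohort <- generate_cohort(cfg)
#' nrow(cohort$samples)
#' @export
generate_cohort <- function(config, catalog = load_catalog()) {
  stopifnot(inherits(config, "sim_config"))
  pv <- config$planted
  if (nrow(pv)) {
    bad <- setdiff(pv$gene, catalog$symbol)
    if (length(bad)) {
      abort(paste0("planted variant outside any catalog gene: ", paste(bad, collapse = ", ")))
    }
    regions <- build_bed(catalog)
    inside <- intersect_variants(pv %>% select("contig", "pos"), regions)
    if (nrow(inside) < nrow(pv)) {
      abort("planted variant position lies outside the catalog gene regions")
    }
  }
  n <- config$n_samples
  old <- .Random.seed_exists()
  set.seed(config$seed)
  on.exit(restore_seed(old), add = TRUE)

  sample_id <- sprintf("S%05d", seq_len(n))
  # family structure: each sample either founds a family or joins an earlier one
  family_id <- character(n)
  fam_count <- 0L
  join <- runif(n) < config$family_rate
  for (i in seq_len(n)) {
    if (i > 1 && join[i] && fam_count > 0L) {
      family_id[i] <- family_id[sample.int(i - 1L, 1L)]
    } else {
      fam_count <- fam_count + 1L
      family_id[i] <- sprintf("F%05d", fam_count)
    }
  }
  # consanguineous partners: symmetric links between unpartnered samples of
  # different families
  partner_id <- rep(NA_character_, n)
  is_partner <- runif(n) < config$consanguinity_rate
  for (i in seq_len(n)) {
    if (i > 1 && is_partner[i] && is.na(partner_id[i])) {
      cand <- which(is.na(partner_id[seq_len(i - 1L)]) &
                      family_id[seq_len(i - 1L)] != family_id[i])
      if (length(cand)) {
        j <- cand[sample.int(length(cand), 1L)]
        partner_id[i] <- sample_id[j]
        partner_id[j] <- sample_id[i]
      }
    }
  }
  sample_type <- ifelse(runif(n) < config$prenatal_rate,
                        sample(c("prenatal", "foetal"), n, replace = TRUE), "postnatal")
  sex <- ifelse(runif(n) < config$male_fraction, "M", "F")
  municipality <- sample(config$municipalities$code, n, replace = TRUE,
                         prob = config$municipality_weights)
  samples <- tibble(sample_id, family_id, partner_id, municipality, sample_type, sex)

  genotypes <- draw_genotypes(samples, pv, config$qc_noise)
  truth <- build_truth(samples, pv, genotypes)
  structure(list(samples = samples, genotypes = genotypes, planted = pv, truth = truth),
            class = "sim_cohort")
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Draw per-sample genotypes at every planted variant. X-linked calls in males
# become hemizygous with probability het_freq + hom_freq.
draw_genotypes <- function(samples, pv, qc_noise) {
  empty <- tibble(
    sample_id = character(), contig = character(), pos = integer(),
    ref = character(), alt = character(), zygosity = character(),
    dp = integer(), gq = integer()
  )
  if (nrow(pv) == 0 || nrow(samples) == 0) return(empty)
  n <- nrow(samples)
  out <- purrr::pmap(
    list(pv$contig, pv$pos, pv$ref, pv$alt, pv$het_freq, pv$hom_freq),
    function(contig, pos, ref, alt, het_freq, hom_freq) {
      u <- runif(n)
      if (contig == "X") {
        male <- samples$sex == "M"
        zyg <- ifelse(male,
                      ifelse(u < het_freq + hom_freq, "hemi", "ref"),
                      ifelse(u < hom_freq, "hom", ifelse(u < hom_freq + het_freq, "het", "ref")))
      } else {
        zyg <- ifelse(u < hom_freq, "hom", ifelse(u < hom_freq + het_freq, "het", "ref"))
      }
      keep <- zyg != "ref"
      if (!any(keep)) return(NULL)
      tibble(
        sample_id = samples$sample_id[keep], contig = contig, pos = pos,
        ref = ref, alt = alt, zygosity = zyg[keep]
      )
    }
  )
  gt <- bind_rows(out)
  if (nrow(gt) == 0) return(empty)
  m <- nrow(gt)
  gt$dp <- sample(20:100, m, replace = TRUE)
  gt$gq <- sample(60:99, m, replace = TRUE)
  # QC noise: push DP or GQ just below the default thresholds
  fail <- runif(m) < qc_noise
  which_metric <- runif(m) < 0.5
  gt$dp[fail & which_metric] <- 9L
  gt$gq[fail & !which_metric] <- 59L
  gt
}

# Expected screening stage implied by an annotation profile.
profile_stage <- function(profile) {
  c(internal_db = "auto_include_internal",
    clinvar_2star_path = "auto_include_clinvar",
    clinvar_2star_benign = "exclude_benign_clinvar",
    high_maf = "exclude_maf",
    low_impact = "exclude_low_impact",
    needs_curation = "needs_curation")[profile]
}

# Tally expected post-QC aggregate counts per planted variant directly from
# the emitted genotype calls.
build_truth <- function(samples, pv, genotypes) {
  n <- nrow(samples)
  n_f <- sum(samples$sex == "F")
  n_m <- n - n_f
  if (nrow(pv) == 0) {
    return(list(
      variants = tibble(
        contig = character(), pos = integer(), ref = character(), alt = character(),
        gene = character(), expected_stage = character(), n_het = integer(),
        n_hom = integer(), n_hemi = integer(), n_missing = integer(),
        ac = integer(), an = integer()
      ),
      n_samples = n
    ))
  }
  pass <- genotypes %>% mutate(qc = qc_pass(.data$dp, .data$gq))
  counts <- pass %>%
    left_join(samples %>% select("sample_id", "sex"), by = "sample_id") %>%
    group_by(.data$contig, .data$pos, .data$ref, .data$alt) %>%
    summarise(
      n_het = sum(.data$qc & .data$zygosity == "het"),
      n_hom = sum(.data$qc & .data$zygosity == "hom"),
      n_hemi = sum(.data$qc & .data$zygosity == "hemi"),
      miss_f = sum(!.data$qc & .data$sex == "F"),
      miss_m = sum(!.data$qc & .data$sex == "M"),
      .groups = "drop"
    )
  tv <- pv %>%
    left_join(counts, by = c("contig", "pos", "ref", "alt")) %>%
    mutate(across(c("n_het", "n_hom", "n_hemi", "miss_f", "miss_m"),
                  ~ tidyr::replace_na(.x, 0L))) %>%
    mutate(
      expected_stage = unname(profile_stage(.data$annotation_profile)),
      ac = 2L * .data$n_hom + .data$n_het + .data$n_hemi,
      an = if_else(.data$contig == "X",
                   2L * (n_f - .data$miss_f) + (n_m - .data$miss_m),
                   2L * (n - .data$miss_f - .data$miss_m)),
      n_missing = .data$miss_f + .data$miss_m
    ) %>%
    select("contig", "pos", "ref", "alt", "gene", "truth_class", "novel",
           "expected_stage", "n_het", "n_hom", "n_hemi", "n_missing", "ac", "an")
  list(variants = tv, n_samples = n)
}

#' Write one VCF per sample
#'
#' Emits minimal standards-conformant single-sample VCF v4.2 files
#' (GT/DP/GQ in FORMAT; contigs without a "chr" prefix). Samples with no
#' non-reference calls yield a header-only VCF. Files round-trip through
#' [read_sample_vcf()].
#'
#' @param cohort A `sim_cohort` from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Tibble with `sample_id` and `path` of the written files.
#' @export
write_single_sample_vcfs <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  contigs <- sort(unique(c(cohort$planted$contig, cohort$genotypes$contig)))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sfscreen-simulator",
    paste0("##contig=<ID=", contigs, ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">'
  )
  gt_string <- c(het = "0/1", hom = "1/1", hemi = "1")
  paths <- purrr::map_chr(cohort$samples$sample_id, function(sid) {
    path <- file.path(dir, paste0(sid, ".vcf"))
    calls <- cohort$genotypes %>% filter(.data$sample_id == sid) %>%
      arrange(.data$contig, .data$pos)
    lines <- c(
      header,
      paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sid)
    )
    if (nrow(calls)) {
      lines <- c(lines, sprintf(
        "%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:DP:GQ\t%s:%d:%d",
        calls$contig, calls$pos, calls$ref, calls$alt,
        gt_string[calls$zygosity], calls$dp, calls$gq
      ))
    }
    ok <- tryCatch({
      writeLines(lines, path)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) abort(paste0("failed to write VCF: ", path))
    path
  })
  tibble(sample_id = cohort$samples$sample_id, path = paths)
}

#' Generate mock annotation tables for planted variants
#'
#' Produces the five knowledge-base tables the screening cascade consumes —
#' internal laboratory classifications, ClinVar-style assertions with review
#' stars, HGMD-style presence flags, gnomAD-style global allele frequencies,
#' and molecular-consequence impact terms — such that each variant's rows
#' realize its `annotation_profile` (e.g., `clinvar_2star_path` yields a
#' two-star PAT assertion; `high_maf` draws a global allele frequency in
#' \[0.005, 0.5\]; `novel` variants get no ClinVar or HGMD rows).
#'
#' @param planted Planted-variant tibble from [plant_variants()].
#' @param seed Integer seed for the drawn allele frequencies.
#' @return List of tibbles `internal`, `clinvar`, `hgmd`, `gnomad`, `impact`,
#'   all keyed by `contig`, `pos`, `ref`, `alt`.
#' @export
generate_annotation_db <- function(planted, seed = 1L) {
  profiles <- c("internal_db", "clinvar_2star_path", "clinvar_2star_benign",
                "high_maf", "low_impact", "needs_curation")
  if (nrow(planted)) {
    bad <- setdiff(planted$annotation_profile, profiles)
    if (length(bad)) abort(paste0("unknown annotation_profile: ", paste(bad, collapse = ", ")))
    contradict <- planted$annotation_profile == "clinvar_2star_path" &
      !planted$truth_class %in% c("PAT", "L-PAT")
    contradict <- contradict | (planted$annotation_profile == "clinvar_2star_benign" &
                                  !planted$truth_class %in% c("BEN", "L-BEN"))
    contradict <- contradict | (planted$annotation_profile %in%
                                  c("clinvar_2star_path", "clinvar_2star_benign") & planted$novel)
    if (any(contradict)) {
      abort("annotation_profile contradicts truth_class/novel flag for a planted variant")
    }
  }
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  key <- planted %>% select("contig", "pos", "ref", "alt")
  p <- planted$annotation_profile
  internal <- key[p == "internal_db", ] %>%
    mutate(internal_class = planted$truth_class[p == "internal_db"])
  has_clinvar <- p %in% c("clinvar_2star_path", "clinvar_2star_benign") |
    (!planted$novel & p %in% c("high_maf", "low_impact"))
  clinvar <- key[has_clinvar, ] %>%
    mutate(
      clinvar_class = dplyr::case_when(
        p[has_clinvar] == "clinvar_2star_path" ~ planted$truth_class[has_clinvar],
        p[has_clinvar] == "clinvar_2star_benign" ~ planted$truth_class[has_clinvar],
        TRUE ~ "VUS"
      ),
      clinvar_stars = if_else(p[has_clinvar] %in% c("clinvar_2star_path", "clinvar_2star_benign"),
                              2L, 1L),
      clinvar_id = as.character(100000L + which(has_clinvar))
    )
  # every non-novel variant is present in the HGMD mock, so that novelty is
  # exactly "absent from both ClinVar and HGMD"
  hgmd <- key[!planted$novel, ] %>% mutate(in_hgmd = TRUE)
  af <- dplyr::case_when(
    p == "high_maf" ~ runif(nrow(planted), 0.005, 0.5),
    TRUE ~ runif(nrow(planted), 0, 0.004)
  )
  gnomad <- key %>% mutate(gnomad_af_global = af)
  impact <- key %>%
    mutate(impact_term = if_else(p == "low_impact", "synonymous_variant", "missense_variant"),
           hgvs_c = planted$hgvs_c,
           hgvs_p = if_else(p == "low_impact", NA_character_,
                            paste0("p.(Arg", .data$pos %% 997L + 1L, "Cys)")))
  list(internal = internal, clinvar = clinvar, hgmd = hgmd, gnomad = gnomad, impact = impact)
}

#' Build a census table with population proportions
#'
#' @param municipalities Tibble with `code` and `population` columns.
#' @return Tibble `code`, `population`, `proportion` (proportions sum to 1).
#' @examples
#' generate_census_table(tibble::tibble(code = c("A", "B"), population = c(100, 300)))
#' @export
generate_census_table <- function(municipalities) {
  stopifnot(all(c("code", "population") %in% names(municipalities)))
  if (anyDuplicated(municipalities$code)) abort("duplicate municipality codes")
  if (any(municipalities$population <= 0)) abort("municipality populations must be > 0")
  municipalities %>%
    as_tibble() %>%
    mutate(proportion = .data$population / sum(.data$population))
}

#' Write the synthetic cohort's side tables
#'
#' Writes the sample-metadata TSV, the census TSV, the five annotation TSVs,
#' and the truth set as JSON, alongside the per-sample VCFs written by
#' [write_single_sample_vcfs()].
#'
#' @param cohort A `sim_cohort`.
#' @param annotations Annotation list from [generate_annotation_db()].
#' @param census Census tibble from [generate_census_table()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort_tables <- function(cohort, annotations, census, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(cohort$samples, file.path(dir, "samples.tsv"), progress = FALSE)
  readr::write_tsv(census, file.path(dir, "census.tsv"), progress = FALSE)
  for (nm in names(annotations)) {
    readr::write_tsv(annotations[[nm]], file.path(dir, paste0(nm, ".tsv")), progress = FALSE)
  }
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
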