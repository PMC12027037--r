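#' Genotype-call quality control
#'
#' A call passes QC iff its read depth and genotype quality both reach the
#' thresholds (defaults DP >= 10x and GQ >= 60; calls below either are
#' excluded from all downstream counting).
#'
#' @param read_depth,genotype_quality Integer vectors of per-call metrics.
#' @param min_depth,min_gq Inclusive thresholds.
#' @return Logical vector.
#' @examples
#' qc_pass(c(10, 9, 0), c(60, 99, 0)) # TRUE FALSE FALSE
#' @export
qc_pass <- function(read_depth, genotype_quality, min_depth = 10L, min_gq = 60L) {
  read_depth >= min_depth & genotype_quality >= min_gq
}

#' Read a single-sample VCF into a genotype tibble
#'
#' Parses a VCF v4.2 file (via vcfR), splits multi-allelic records into
#' biallelic keys, normalizes keys to their minimal left-aligned
#' representation, and maps GT strings to zygosity (`0/1` or `1/0` het,
#' `1/1` hom, `1` hemi, `./.` missing; phased separators accepted;
#' `0/0` rows are dropped).
#'
#' @param path Path to the VCF file.
#' @return Tibble `sample_id`, `contig`, `pos`, `ref`, `alt`, `zygosity`,
#'   `dp`, `gq`.
#' @export
read_sample_vcf <- function(path) {
  if (!file.exists(path)) abort(paste0("VCF not found: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  empty <- tibble(
    sample_id = character(), contig = character(), pos = integer(),
    ref = character(), alt = character(), zygosity = character(),
    dp = integer(), gq = integer()
  )
  if (nrow(v@fix) == 0) {
    sid <- colnames(v@gt)[-1] %||% character()
    if (length(sid) == 0) return(empty)
    return(empty)
  }
  sid <- colnames(v@gt)[2]
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(as.integer(vcfR::extract.gt(v, element = "DP")[, 1]))
  gq <- suppressWarnings(as.integer(vcfR::extract.gt(v, element = "GQ")[, 1]))
  rec <- tibble(
    contig = as.character(v@fix[, "CHROM"]),
    pos = as.integer(v@fix[, "POS"]),
    ref = as.character(v@fix[, "REF"]),
    alt = as.character(v@fix[, "ALT"]),
    gt = as.character(gt[, 1]),
    dp = tidyr::replace_na(dp, 0L),
    gq = tidyr::replace_na(gq, 0L)
  )
  # split multi-allelic records into biallelic keys; the genotype index
  # selects which ALT each row refers to
  rec <- rec %>%
    mutate(.row = row_number()) %>%
    tidyr::separate_longer_delim("alt", delim = ",") %>%
    group_by(.data$.row) %>%
    mutate(.alt_idx = row_number()) %>%
    ungroup()
  gtn <- gsub("\\|", "/", rec$gt)
  alleles <- strsplit(gtn, "/", fixed = TRUE)
  zyg <- purrr::map2_chr(alleles, rec$.alt_idx, function(a, idx) {
    if (any(a == ".")) return("missing")
    a <- as.integer(a)
    hits <- sum(a == idx)
    if (length(a) == 1) {
      if (hits == 1) "hemi" else "ref"
    } else if (hits == 2) {
      "hom"
    } else if (hits == 1) {
      "het"
    } else {
      "ref"
    }
  })
  rec$zygosity <- zyg
  rec <- rec %>% filter(.data$zygosity != "ref")
  if (nrow(rec) == 0) return(empty)
  rec %>%
    normalize_keys() %>%
    mutate(sample_id = sid) %>%
    select("sample_id", "contig", "pos", "ref", "alt", "zygosity", "dp", "gq")
}

#' Merge single-sample VCFs into a cohort genotype table
#'
#' Reads each VCF, applies genotype QC (failing calls become missing calls,
#' reducing the called allele number rather than counting as reference),
#' restricts to the screening regions, and returns the union of variant keys
#' with per-sample zygosity. Samples with no record at a retained site are
#' implicitly homozygous reference there.
#'
#' @param vcf_paths Character vector of single-sample VCF paths, or a tibble
#'   with a `path` column as returned by [write_single_sample_vcfs()].
#' @param regions Screening regions from [build_bed()].
#' @param min_depth,min_gq QC thresholds passed to [qc_pass()].
#' @return Tibble of class `genotype_table`: `sample_id`, `contig`, `pos`,
#'   `ref`, `alt`, `gene`, `zygosity` (het/hom/hemi/missing), with the
#'   cohort's sample ids attached as an attribute.
#' @export
merge_multisample <- function(vcf_paths, regions, min_depth = 10L, min_gq = 60L) {
  if (is.data.frame(vcf_paths)) vcf_paths <- vcf_paths$path
  calls <- purrr::map_dfr(vcf_paths, read_sample_vcf)
  sample_ids <- unique(purrr::map_chr(vcf_paths, function(p) {
    hdr <- readLines(p, warn = FALSE)
    col <- grep("^#CHROM", hdr, value = TRUE)[1]
    utils::tail(strsplit(col, "\t", fixed = TRUE)[[1]], 1)
  }))
  genotype_table(calls, regions, sample_ids, min_depth = min_depth, min_gq = min_gq)
}

#' Build a QC-masked, region-restricted genotype table
#'
#' The in-memory counterpart of [merge_multisample()]: accepts a long tibble
#' of genotype calls (e.g. the `genotypes` element of a `sim_cohort`) and
#' applies the same QC masking and region restriction.
#'
#' @param calls Tibble with `sample_id`, `contig`, `pos`, `ref`, `alt`,
#'   `zygosity`, `dp`, `gq`.
#' @param regions Screening regions from [build_bed()].
#' @param sample_ids All sample ids in the cohort (samples without calls
#'   still contribute reference alleles).
#' @param min_depth,min_gq QC thresholds.
#' @return A `genotype_table` tibble (see [merge_multisample()]).
#' @export
genotype_table <- function(calls, regions, sample_ids, min_depth = 10L, min_gq = 60L) {
  conflicts <- calls %>%
    distinct(.data$contig, .data$pos, .data$ref) %>%
    count(.data$contig, .data$pos) %>%
    filter(.data$n > 1)
  if (nrow(conflicts)) {
    abort(paste0("conflicting REF alleles at ", conflicts$contig[1], ":", conflicts$pos[1]))
  }
  masked <- calls %>%
    mutate(zygosity = if_else(qc_pass(.data$dp, .data$gq, min_depth, min_gq),
                              .data$zygosity, "missing")) %>%
    select("sample_id", "contig", "pos", "ref", "alt", "zygosity")
  kept <- intersect_variants(masked, regions)
  structure(kept, class = c("genotype_table", class(kept)),
            sample_ids = unique(sample_ids))
}

#' Anonymized aggregate counts per variant
#'
#' Collapses a genotype table into cohort-level counts and removes all
#' individual-level information: allele count (`ac = 2*n_hom + n_het +
#' n_hemi`), called allele number `an` (reference samples included; missing
#' calls reduce it; on the X chromosome males contribute one allele and
#' females two), allele frequency `af = ac/an`, and zygosity counts. Sites
#' where every call is missing have `an = 0` and are dropped with a notice.
#'
#' @param genotypes A `genotype_table` from [merge_multisample()] or
#'   [genotype_table()].
#' @param sex_map Tibble `sample_id`, `sex` ("M"/"F") covering all samples;
#'   required to count X-chromosome alleles. May be NULL for all-autosomal
#'   data.
#' @return Tibble with one row per variant: `contig`, `pos`, `ref`, `alt`,
#'   `gene`, `ac`, `an`, `af`, `n_hom`, `n_het`, `n_hemi`, `table_total`
#'   (= n_hom + n_het + n_hemi, the observation count). No sample
#'   identifiers appear in the output.
#' @export
aggregate_genotypes <- function(genotypes, sex_map = NULL) {
  sample_ids <- attr(genotypes, "sample_ids")
  if (is.null(sample_ids)) abort("genotypes must come from merge_multisample()/genotype_table()")
  n <- length(sample_ids)
  has_x <- any(genotypes$contig == "X")
  if (has_x && is.null(sex_map)) {
    abort("sex_map is required when X-chromosome variants are present")
  }
  if (!is.null(sex_map)) {
    missing_sex <- setdiff(sample_ids, sex_map$sample_id)
    if (length(missing_sex)) abort("sex_map does not cover all samples")
    n_f <- sum(sex_map$sex[match(sample_ids, sex_map$sample_id)] == "F")
  } else {
    n_f <- n
  }
  n_m <- n - n_f
  g <- genotypes
  if (!is.null(sex_map)) {
    g <- g %>% left_join(sex_map %>% select("sample_id", "sex"), by = "sample_id")
  } else {
    g <- g %>% mutate(sex = "F")
  }
  agg <- g %>%
    group_by(.data$contig, .data$pos, .data$ref, .data$alt, .data$gene) %>%
    summarise(
      n_het = sum(.data$zygosity == "het"),
      n_hom = sum(.data$zygosity == "hom"),
      n_hemi = sum(.data$zygosity == "hemi"),
      miss_f = sum(.data$zygosity == "missing" & .data$sex == "F"),
      miss_m = sum(.data$zygosity == "missing" & .data$sex == "M"),
      .groups = "drop"
    ) %>%
    mutate(
      ac = 2L * .data$n_hom + .data$n_het + .data$n_hemi,
      an = if_else(.data$contig == "X",
                   2L * (n_f - .data$miss_f) + (n_m - .data$miss_m),
                   2L * (n - .data$miss_f - .data$miss_m)),
      af = if_else(.data$an > 0, .data$ac / .data$an, NA_real_),
      table_total = .data$n_hom + .data$n_het + .data$n_hemi
    ) %>%
    select("contig", "pos", "ref", "alt", "gene", "ac", "an", "af",
           "n_hom", "n_het", "n_hemi", "table_total") %>%
    arrange(.data$contig, .data$pos, .data$ref, .data$alt)
  dropped <- agg %>% filter(.data$an == 0)
  if (nrow(dropped)) {
    inform(paste0(nrow(dropped), " site(s) with all calls missing dropped (an = 0)"))
    agg <- agg %>% filter(.data$an > 0)
  }
  structure(agg, n_samples = n, n_female = n_f, n_male = n_m)
}

#' Write aggregate variants as an anonymized VCF-style TSV
#'
#' @param aggregates Tibble from [aggregate_genotypes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aggregate <- function(aggregates, path) {
  readr::write_tsv(as_tibble(aggregates), path, progress = FALSE)
  invisible(path)
}
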