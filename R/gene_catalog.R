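#' Load the ACMG v3.2 actionable-gene catalog
#'
#' Reads the bundled catalog of the 81 genes for which reporting of secondary
#' findings is recommended (ACMG SF v3.2), with phenotype group, associated
#' disease, inheritance mode (AD/AR/XL), transcript, and exon coordinates.
#' The bundled gene models are synthetic: exon coordinates live on toy
#' contigs, since only interval logic (not genome positions) matters for the
#' screening pipeline. A table derived from a real annotation (same columns)
#' can be supplied via `path`.
#'
#' @param path Optional path to a catalog TSV with columns `symbol`,
#'   `phenotype_group`, `disease`, `inheritance`, `transcript`, `contig`,
#'   `exon_starts`, `exon_ends` (comma-separated 1-based inclusive
#'   coordinates). Defaults to the bundled ACMG v3.2 table.
#' @return A tibble with one row per gene; `exon_start` and `exon_end` are
#'   list-columns of sorted integer vectors.
#' @examples
#' catalog <- load_catalog()
#' nrow(catalog) # 81
#' dplyr::count(catalog, phenotype_group)
#' @export
load_catalog <- function(path = NULL) {
  path <- path %||% system.file("extdata", "acmg_sf32_catalog.tsv", package = "sfscreen")
  if (!nzchar(path) || !file.exists(path)) {
    abort("gene catalog file not found")
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  needed <- c("symbol", "phenotype_group", "disease", "inheritance", "transcript",
              "contig", "exon_starts", "exon_ends")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    abort(paste0("catalog is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  bad_inh <- raw$symbol[!raw$inheritance %in% c("AD", "AR", "XL")]
  if (length(bad_inh)) {
    abort(paste0("invalid inheritance mode for: ", paste(bad_inh, collapse = ", ")))
  }
  if (anyDuplicated(raw$symbol)) {
    abort(paste0("duplicated gene symbol: ", raw$symbol[duplicated(raw$symbol)][1]))
  }
  parse_ints <- function(x) lapply(strsplit(x, ","), function(v) as.integer(v))
  cat <- raw %>%
    mutate(
      exon_start = parse_ints(.data$exon_starts),
      exon_end = parse_ints(.data$exon_ends)
    ) %>%
    select(-"exon_starts", -"exon_ends")
  for (i in seq_len(nrow(cat))) {
    s <- cat$exon_start[[i]]
    e <- cat$exon_end[[i]]
    if (length(s) != length(e) || any(is.na(s)) || any(is.na(e)) || any(e < s) ||
        is.unsorted(s, strictly = TRUE) || any(s[-1] <= e[-length(e)])) {
      abort(paste0("malformed exon list for gene ", cat$symbol[i]))
    }
  }
  cat
}

#' Exons of a catalog as a long tibble
#'
#' @param catalog A catalog from [load_catalog()].
#' @return Tibble with one row per exon: `symbol`, `contig`, `start`, `end`
#'   (1-based inclusive).
#' @export
catalog_exons <- function(catalog) {
  catalog %>%
    select("symbol", "contig", "exon_start", "exon_end") %>%
    tidyr::unnest(c("exon_start", "exon_end")) %>%
    rename(start = "exon_start", end = "exon_end")
}

#' Build the screening region set (BED intervals) from a catalog
#'
#' Expands each exon by `flank_bp` intronic flanking bases on both sides
#' (default 20 bp, the convention used when restricting exome variants to
#' coding regions of the actionable genes), converts to 0-based half-open
#' BED coordinates, and merges overlapping padded intervals within a gene.
#'
#' @param catalog A catalog from [load_catalog()].
#' @param flank_bp Non-negative integer flank added to each exon side.
#' @return Tibble of regions: `contig`, `start` (0-based), `end` (exclusive),
#'   `gene`.
#' @examples
#' bed <- build_bed(load_catalog(), flank_bp = 20)
#' @export
build_bed <- function(catalog, flank_bp = 20L) {
  stopifnot(length(flank_bp) == 1, flank_bp >= 0)
  flank_bp <- as.integer(flank_bp)
  ex <- catalog_exons(catalog) %>%
    mutate(
      bed_start = .data$start - 1L - flank_bp,
      bed_end = .data$end + flank_bp
    )
  if (any(ex$bed_start < 0)) {
    warn("flanked interval extends past contig start; clamped to 0")
    ex$bed_start <- pmax(ex$bed_start, 0L)
  }
  # merge overlapping/adjacent padded exons within a gene
  ex %>%
    arrange(.data$symbol, .data$bed_start) %>%
    group_by(.data$symbol, .data$contig) %>%
    mutate(grp = cumsum(.data$bed_start > dplyr::lag(cummax(.data$bed_end), default = -1L))) %>%
    group_by(.data$symbol, .data$contig, .data$grp) %>%
    summarise(start = min(.data$bed_start), end = max(.data$bed_end), .groups = "drop") %>%
    select(contig = "contig", start = "start", end = "end", gene = "symbol") %>%
    arrange(.data$contig, .data$start)
}

#' Write a region set as a BED file
#'
#' @param regions Regions from [build_bed()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  readr::write_tsv(regions %>% select("contig", "start", "end", "gene"),
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Restrict variants to the screening regions
#'
#' Keeps variants whose 1-based VCF position falls inside a region
#' (`start < pos <= end` in 0-based half-open BED coordinates — i.e., the
#' anchor base of an indel decides membership). Input order is preserved and
#' the matched gene symbol is attached.
#'
#' @param variants Tibble with columns `contig`, `pos` (1-based), and any
#'   others, which are carried through.
#' @param regions Regions from [build_bed()].
#' @return The subset of `variants` inside the regions, with a `gene` column.
#' @examples
#' regions <- tibble::tibble(contig = "1", start = 80L, end = 220L, gene = "GENE1")
#' v <- tibble::tibble(contig = "1", pos = c(80L, 81L, 220L, 221L))
#' intersect_variants(v, regions)$pos # 81 and 220 are kept
#' @export
intersect_variants <- function(variants, regions) {
  if (nrow(variants) == 0) {
    return(variants %>% mutate(gene = character(0)))
  }
  variants <- variants %>% mutate(.ord = row_number())
  hits <- variants %>%
    inner_join(regions, by = "contig", relationship = "many-to-many") %>%
    filter(.data$start < .data$pos, .data$pos <= .data$end) %>%
    distinct(.data$.ord, .keep_all = TRUE) %>%
    select(-"start", -"end")
  hits %>% arrange(.data$.ord) %>% select(-".ord")
}
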