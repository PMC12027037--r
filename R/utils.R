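#' sfscreen: secondary-findings screening of exome cohorts
#'
#' Tools to estimate the frequency of medically actionable secondary findings
#' and of recessive-disease carriers from cohort exome data screened against
#' the ACMG v3.2 catalog of 81 actionable genes.
#'
#' @importFrom dplyr mutate filter select arrange summarise group_by ungroup
#'   left_join inner_join anti_join semi_join bind_rows distinct n rename
#'   row_number across case_when pull count first slice if_else %>%
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data %||% abort warn inform
#' @importFrom stats runif setNames
#' @importFrom utils head
#' @keywords internal
"_PACKAGE"

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# Five-tier ACMG/AMP classification vocabulary used throughout.
CLASS_LEVELS <- c("PAT", "L-PAT", "VUS", "L-BEN", "BEN")

# Terminal stages of the screening cascade, in decision order.
SCREEN_STAGES <- c(
  "auto_include_internal", "auto_include_clinvar", "exclude_benign_clinvar",
  "exclude_maf", "exclude_low_impact", "needs_curation",
  "curated_include", "curated_exclude"
)

INCLUDED_STAGES <- c("auto_include_internal", "auto_include_clinvar", "curated_include")

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used for all printed percentages:
#' `round_half_up(2.5, 0)` is 3, unlike [round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(c(0.125, 0.135), 2)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  trunc(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p * sign(x)
}

#' Canonical string form of a variant key
#'
#' @param contig,pos,ref,alt Components of a normalized variant key.
#' @return Character vector `"contig:pos:ref:alt"`.
#' @export
variant_id <- function(contig, pos, ref, alt) {
  paste(contig, pos, ref, alt, sep = ":")
}

#' Normalize variant keys to minimal left-aligned representation
#'
#' Trims shared trailing then leading bases from REF/ALT (keeping at least one
#' base of each) and adjusts POS, so that equivalent indel spellings compare
#' equal before merging.
#'
#' @param keys Tibble with columns `contig`, `pos`, `ref`, `alt`.
#' @return The tibble with normalized `pos`, `ref`, `alt`.
#' @export
normalize_keys <- function(keys) {
  stopifnot(all(c("contig", "pos", "ref", "alt") %in% names(keys)))
  norm1 <- function(pos, ref, alt) {
    if (ref == alt) abort("variant with ref == alt is not a variant")
    r <- strsplit(ref, "")[[1]]
    a <- strsplit(alt, "")[[1]]
    # shared suffix
    while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]
      a <- a[-length(a)]
    }
    # shared prefix
    while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
      r <- r[-1]
      a <- a[-1]
      pos <- pos + 1L
    }
    list(pos = pos, ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
  }
  out <- purrr::pmap(list(keys$pos, keys$ref, keys$alt), norm1)
  keys$pos <- purrr::map_int(out, ~ as.integer(.x$pos))
  keys$ref <- purrr::map_chr(out, ~ .x$ref)
  keys$alt <- purrr::map_chr(out, ~ .x$alt)
  keys
}
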