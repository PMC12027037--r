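test_that("the cascade applies its rules in priority order", {
  # internal assertion outranks a high population frequency
  d <- screen_variants(ann_record(internal_class = "PAT", gnomad_af_global = 0.02))
  expect_equal(d$stage, "auto_include_internal")
  expect_equal(d$final_class, "PAT")
  expect_true(d$included)

  # two-star benign ClinVar assertion excludes
  d <- screen_variants(ann_record(clinvar_class = "L-BEN", clinvar_stars = 2L))
  expect_equal(d$stage, "exclude_benign_clinvar")
  expect_false(d$included)

  # frequency at or above the cutoff excludes when not excepted
  d <- screen_variants(ann_record(gnomad_af_global = 0.006))
  expect_equal(d$stage, "exclude_maf")
  d <- screen_variants(ann_record(gnomad_af_global = 0.005))
  expect_equal(d$stage, "exclude_maf") # closed bound
  d <- screen_variants(ann_record(gnomad_af_global = 0.0049))
  expect_equal(d$stage, "needs_curation")

  # one-star ClinVar assertions carry no weight
  d <- screen_variants(ann_record(clinvar_class = "PAT", clinvar_stars = 1L))
  expect_equal(d$stage, "needs_curation")

  # low-impact consequence excludes; unknown terms retained conservatively
  d <- screen_variants(ann_record(impact_term = "synonymous_variant"))
  expect_equal(d$stage, "exclude_low_impact")
  d <- screen_variants(ann_record(impact_term = "some_future_term"))
  expect_equal(d$stage, "needs_curation")

  # no evidence at all falls through to curation
  d <- screen_variants(ann_record(gnomad_af_global = 0.001))
  expect_equal(d$stage, "needs_curation")
})

test_that("the HFE p.Cys282Tyr variant is exempt from the MAF exclusion", {
  hfe <- ann_record(gnomad_af_global = 0.05, hgvs_c = "NM_000410.4:c.845G>A")
  d <- screen_variants(hfe)
  expect_false(d$stage == "exclude_maf")
  expect_equal(d$stage, "needs_curation")
  # the same record without the exception is excluded
  d2 <- screen_variants(hfe, exceptions = character())
  expect_equal(d2$stage, "exclude_maf")
})

test_that("an internal VUS does not block a two-star pathogenic ClinVar assertion", {
  d <- screen_variants(ann_record(internal_class = "VUS", clinvar_class = "PAT",
                                  clinvar_stars = 2L))
  expect_equal(d$stage, "auto_include_clinvar")
  expect_equal(d$final_class, "PAT")
})

test_that("manual curation resolves pending variants by curated class", {
  ann <- dplyr::bind_rows(
    ann_record(pos = 1L),
    ann_record(pos = 2L),
    ann_record(pos = 3L)
  )
  dec <- screen_variants(ann)
  expect_true(all(dec$stage == "needs_curation"))
  cur <- tibble::tibble(contig = "1", pos = c(1L, 2L), ref = "A", alt = "G",
                        curated_class = c("L-PAT", "VUS"))
  out <- apply_curation(dec, cur)
  expect_equal(out$stage, c("curated_include", "curated_exclude", "curated_exclude"))
  expect_equal(out$final_class[1], "L-PAT")
  # absent variants can instead stay pending
  out2 <- apply_curation(dec, cur, absent_pending = TRUE)
  expect_equal(out2$stage[3], "needs_curation")
})

test_that("curation of decided variants is rejected; unknown keys warn", {
  dec <- screen_variants(ann_record(internal_class = "PAT"))
  cur <- tibble::tibble(contig = "1", pos = 100L, ref = "A", alt = "G",
                        curated_class = "VUS")
  expect_error(apply_curation(dec, cur), "not at needs_curation")
  dec2 <- screen_variants(ann_record(pos = 5L))
  stray <- tibble::tibble(contig = "9", pos = 999L, ref = "A", alt = "G",
                          curated_class = "PAT")
  expect_warning(out <- apply_curation(dec2, stray), "ignored")
  expect_equal(out$stage, "curated_exclude")
})

test_that("curated inclusion counts match the curated pathogenic set", {
  ann <- purrr::map_dfr(1:100, ~ ann_record(pos = .x))
  dec <- screen_variants(ann)
  cur <- tibble::tibble(contig = "1", pos = 1:40, ref = "A", alt = "G",
                        curated_class = rep(c("PAT", "L-PAT"), 20))
  out <- apply_curation(dec, cur)
  expect_equal(sum(out$stage == "curated_include"), 40)
  expect_equal(attr(funnel_summary(out), "included_total"), 40)
})

test_that("funnel counts partition the screened variants", {
  expect_true(all(funnel_summary(screen_variants(ann_record()[0, ]))$n == 0))
  cat <- load_catalog()
  pv <- default_planted(cat)
  ann <- collate_annotations(generate_annotation_db(pv, seed = 2), variants = pv)
  dec <- screen_variants(ann)
  fs <- funnel_summary(dec)
  expect_equal(sum(fs$n), nrow(dec))
  expect_equal(attr(fs, "n_screened"), nrow(dec))
  expect_equal(attr(fs, "included_total"), sum(dec$included))
})

test_that("screening is order-invariant and monotone in the MAF cutoff", {
  set.seed(55)
  n <- 120
  ann <- tibble::tibble(
    contig = "1", pos = seq_len(n), ref = "A", alt = "G",
    internal_class = sample(c(NA, sfscreen:::CLASS_LEVELS), n, replace = TRUE),
    clinvar_class = sample(c(NA, sfscreen:::CLASS_LEVELS), n, replace = TRUE),
    in_hgmd = sample(c(TRUE, FALSE), n, replace = TRUE),
    gnomad_af_global = ifelse(runif(n) < 0.2, NA, runif(n, 0, 0.02)),
    impact_term = sample(c("missense_variant", "synonymous_variant", "stop_gained"),
                         n, replace = TRUE),
    hgvs_c = NA_character_, hgvs_p = NA_character_, clinvar_id = NA_character_
  )
  ann$clinvar_stars <- ifelse(is.na(ann$clinvar_class), NA_integer_,
                              sample(0:4, n, replace = TRUE))
  base <- screen_variants(ann)
  # permuting the input rows never changes any variant's stage
  perm <- sample.int(n)
  shuffled <- screen_variants(ann[perm, ])
  expect_equal(shuffled$stage, base$stage[perm])
  expect_equal(sum(funnel_summary(base)$n), n)
  # lowering the cutoff can only move variants out via the MAF rule,
  # never from included to excluded
  for (cutoff in c(0.003, 0.001, 0.0005)) {
    lower <- screen_variants(ann, maf_cutoff = cutoff)
    expect_true(all(!(base$included & !lower$included)))
  }
})

test_that("novel variants are included variants unseen in ClinVar and HGMD", {
  ann <- dplyr::bind_rows(
    ann_record(pos = 1L, internal_class = "PAT", in_hgmd = TRUE),
    ann_record(pos = 2L, internal_class = "PAT", in_hgmd = FALSE),
    ann_record(pos = 3L, internal_class = "L-PAT", clinvar_class = "PAT",
               clinvar_stars = 1L),
    ann_record(pos = 4L, gnomad_af_global = 0.01)
  )
  dec <- flag_novel(screen_variants(ann))
  expect_equal(dec$novel, c(FALSE, TRUE, FALSE, NA))
  ns <- novel_summary(dec)
  expect_equal(ns$n_included, 3)
  expect_equal(ns$n_novel, 1)
})

test_that("the funnel plot is a ggplot", {
  dec <- screen_variants(ann_record(internal_class = "PAT"))
  expect_s3_class(plot_funnel(dec), "ggplot")
})
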