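test_that("genotype QC is a closed bound on both metrics", {
  expect_true(qc_pass(10, 60))
  expect_false(qc_pass(9, 99))
  expect_false(qc_pass(100, 59))
  expect_false(qc_pass(0, 0))
  expect_equal(qc_pass(c(10, 9, 50), c(60, 60, 59)), c(TRUE, FALSE, FALSE))
})

make_calls <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(purrr::map(rows, function(r) {
    tibble::tibble(sample_id = r[[1]], contig = r[[2]], pos = as.integer(r[[3]]),
                   ref = r[[4]], alt = r[[5]], zygosity = r[[6]],
                   dp = if (length(r) >= 7) as.integer(r[[7]]) else 50L,
                   gq = if (length(r) >= 8) as.integer(r[[8]]) else 90L)
  }))
}

toy_regions <- tibble::tibble(contig = "1", start = 0L, end = 10000L, gene = "G")

test_that("two samples sharing a het variant merge into one keyed row", {
  calls <- make_calls(list("s1", "1", 100, "A", "G", "het"),
                      list("s2", "1", 100, "A", "G", "het"))
  gt <- genotype_table(calls, toy_regions, sample_ids = c("s1", "s2"))
  expect_equal(nrow(gt), 2)
  expect_equal(unique(gt$pos), 100L)
  expect_equal(gt$zygosity, c("het", "het"))
})

test_that("variants outside the screening regions are dropped", {
  calls <- make_calls(list("s1", "1", 100, "A", "G", "het"),
                      list("s1", "2", 100, "A", "G", "het"))
  gt <- genotype_table(calls, toy_regions, sample_ids = "s1")
  expect_equal(unique(gt$contig), "1")
})

test_that("conflicting REF alleles at one site abort the merge", {
  calls <- make_calls(list("s1", "1", 100, "A", "G", "het"),
                      list("s2", "1", 100, "T", "G", "het"))
  expect_error(genotype_table(calls, toy_regions, sample_ids = c("s1", "s2")),
               "conflicting REF")
})

test_that("multi-sample merge over files reproduces the truth genotype matrix", {
  cat <- load_catalog()
  cohort <- small_cohort(n = 20, seed = 21, catalog = cat, qc_noise = 0.15)
  dir <- withr::local_tempdir()
  files <- write_single_sample_vcfs(cohort, dir)
  gt <- merge_multisample(files, build_bed(cat))
  expected <- cohort$genotypes %>%
    dplyr::mutate(zygosity = dplyr::if_else(qc_pass(dp, gq), zygosity, "missing")) %>%
    dplyr::select(sample_id, contig, pos, ref, alt, zygosity) %>%
    dplyr::left_join(dplyr::distinct(cohort$planted, contig, pos, ref, alt, gene),
                     by = c("contig", "pos", "ref", "alt")) %>%
    dplyr::arrange(sample_id, contig, pos)
  got <- tibble::as_tibble(gt) %>% dplyr::arrange(sample_id, contig, pos)
  expect_equal(got[, names(expected)], expected, ignore_attr = TRUE)
})

test_that("aggregation counts alleles as defined and drops all-missing sites", {
  calls <- make_calls(list("s1", "1", 100, "A", "G", "het"),
                      list("s2", "1", 100, "A", "G", "hom"),
                      list("s3", "1", 100, "A", "G", "het", 9, 99),
                      list("s1", "1", 200, "C", "T", "het", 5, 10),
                      list("s2", "1", 200, "C", "T", "het", 9, 59),
                      list("s3", "1", 200, "C", "T", "hom", 2, 2))
  gt <- genotype_table(calls, toy_regions, sample_ids = c("s1", "s2", "s3"))
  expect_message(agg <- aggregate_genotypes(gt), "all calls missing")
  expect_equal(nrow(agg), 1)
  expect_equal(agg$ac, 3L)
  expect_equal(agg$an, 4L)
  expect_equal(agg$n_hom, 1L)
  expect_equal(agg$n_het, 1L)
  expect_equal(agg$table_total, 2L)
  expect_equal(agg$af, 0.75)
})

test_that("aggregate counts equal an independent per-cell tally on random matrices", {
  set.seed(33)
  n_s <- 50
  n_v <- 30
  sids <- sprintf("s%02d", 1:n_s)
  zyg_levels <- c("ref", "het", "hom", "missing")
  mat <- matrix(sample(zyg_levels, n_s * n_v, replace = TRUE,
                       prob = c(0.6, 0.2, 0.1, 0.1)),
                nrow = n_v, ncol = n_s)
  calls <- purrr::map_dfr(1:n_v, function(v) {
    nonref <- which(mat[v, ] != "ref")
    if (!length(nonref)) return(NULL)
    tibble::tibble(sample_id = sids[nonref], contig = "1", pos = v * 10L,
                   ref = "A", alt = "G", zygosity = mat[v, nonref],
                   dp = dplyr::if_else(mat[v, nonref] == "missing", 5L, 50L),
                   gq = 90L)
  })
  gt <- genotype_table(calls, toy_regions, sample_ids = sids)
  agg <- suppressMessages(aggregate_genotypes(gt))
  for (i in seq_len(nrow(agg))) {
    row <- mat[agg$pos[i] / 10, ]
    expect_equal(agg$n_het[i], sum(row == "het"))
    expect_equal(agg$n_hom[i], sum(row == "hom"))
    expect_equal(agg$ac[i], 2L * sum(row == "hom") + sum(row == "het"))
    expect_equal(agg$an[i], 2L * sum(row != "missing"))
  }
  # conservation holds across the board
  expect_equal(agg$ac, 2L * agg$n_hom + agg$n_het + agg$n_hemi)
  expect_true(all(agg$ac <= agg$an))
  expect_true(all(agg$table_total <= agg$ac))
})

test_that("X-chromosome alleles are counted haploid in males", {
  xregions <- tibble::tibble(contig = "X", start = 0L, end = 10000L, gene = "GX")
  calls <- make_calls(list("m1", "X", 100, "A", "G", "hemi"),
                      list("f1", "X", 100, "A", "G", "het"),
                      list("f2", "X", 100, "A", "G", "hom"))
  gt <- genotype_table(calls, xregions, sample_ids = c("m1", "m2", "f1", "f2"))
  sex <- tibble::tibble(sample_id = c("m1", "m2", "f1", "f2"),
                        sex = c("M", "M", "F", "F"))
  agg <- aggregate_genotypes(gt, sex_map = sex)
  expect_equal(agg$n_hemi, 1L)
  expect_equal(agg$ac, 1L + 1L + 2L)
  expect_equal(agg$an, 2L * 2L + 2L) # two females diploid, two males haploid
  expect_error(aggregate_genotypes(gt), "sex_map")
})

test_that("aggregate output is anonymized: no sample identifier survives", {
  cat <- load_catalog()
  cohort <- small_cohort(n = 15, seed = 8, catalog = cat)
  gt <- genotype_table(cohort$genotypes, build_bed(cat),
                       sample_ids = cohort$samples$sample_id)
  agg <- suppressMessages(
    aggregate_genotypes(gt, sex_map = cohort$samples[, c("sample_id", "sex")])
  )
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_aggregate(agg, tmp)
  serialized <- paste(readLines(tmp, warn = FALSE), collapse = "\n")
  for (sid in cohort$samples$sample_id) {
    expect_false(grepl(sid, serialized, fixed = TRUE))
  }
})

test_that("raising QC thresholds never increases any allele count", {
  cat <- load_catalog()
  cohort <- small_cohort(n = 30, seed = 14, catalog = cat, qc_noise = 0.2)
  bed <- build_bed(cat)
  sex <- cohort$samples[, c("sample_id", "sex")]
  agg_at <- function(min_depth, min_gq) {
    gt <- genotype_table(cohort$genotypes, bed, cohort$samples$sample_id,
                         min_depth = min_depth, min_gq = min_gq)
    suppressMessages(aggregate_genotypes(gt, sex_map = sex))
  }
  base <- agg_at(10, 60)
  for (th in list(c(20, 60), c(10, 80), c(30, 95))) {
    stricter <- agg_at(th[1], th[2])
    joined <- dplyr::left_join(
      tibble::as_tibble(base)[, c("contig", "pos", "ref", "alt", "ac")],
      tibble::as_tibble(stricter)[, c("contig", "pos", "ref", "alt", "ac")],
      by = c("contig", "pos", "ref", "alt"), suffix = c("_base", "_strict")
    ) %>% dplyr::mutate(ac_strict = dplyr::coalesce(ac_strict, 0L))
    expect_true(all(joined$ac_strict <= joined$ac_base))
  }
})

test_that("variant keys are normalized to minimal left-aligned form", {
  keys <- tibble::tibble(contig = "1", pos = c(100L, 100L, 50L),
                         ref = c("ATT", "CAA", "G"), alt = c("AT", "CTA", "GA"))
  norm <- normalize_keys(keys)
  expect_equal(norm$pos, c(100L, 101L, 50L))
  expect_equal(norm$ref, c("AT", "A", "G"))
  expect_equal(norm$alt, c("A", "T", "GA"))
})
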