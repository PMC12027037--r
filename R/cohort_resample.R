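#' Apply diagnostic-cohort exclusion rules
#'
#' Reduces a raw diagnostic cohort to unrelated, postnatal individuals by
#' (i) keeping only one sample per family, (ii) keeping one partner per
#' consanguineous couple, and (iii) removing prenatal and foetal samples.
#' Within a family or couple the retained member is chosen uniformly at
#' random under the seed. Every removed sample is logged with the rule that
#' excluded it; retrieve the log with [exclusion_log()].
#'
#' @param samples Sample-metadata tibble with columns `sample_id`,
#'   `family_id`, `partner_id` (NA when unpartnered), `municipality`,
#'   `sample_type` (`postnatal`, `prenatal`, or `foetal`).
#' @param seed Integer seed for the random choices.
#' @return The retained samples, with the exclusion log attached as an
#'   attribute.
#' @examples
#' s <- tibble::tibble(
#'   sample_id = c("a", "b", "c"), family_id = c("f1", "f1", "f2"),
#'   partner_id = NA_character_, municipality = "M1",
#'   sample_type = c("postnatal", "postnatal", "prenatal")
#' )
#' kept <- apply_exclusions(s, seed = 1)
#' exclusion_log(kept)
#' @export
apply_exclusions <- function(samples, seed) {
  stopifnot(all(c("sample_id", "family_id", "sample_type") %in% names(samples)))
  if (anyDuplicated(samples$sample_id)) abort("duplicate sample ids")
  if (!"partner_id" %in% names(samples)) samples$partner_id <- NA_character_
  pid <- samples$partner_id
  has_p <- which(!is.na(pid))
  partner_row <- match(pid[has_p], samples$sample_id)
  if (any(is.na(partner_row)) ||
      any(pid[partner_row] != samples$sample_id[has_p], na.rm = TRUE) ||
      any(is.na(pid[partner_row]))) {
    abort("partner links must be symmetric")
  }
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  log <- tibble(sample_id = character(), rule = character())
  # (iii) prenatal / foetal samples
  pre <- samples %>% filter(.data$sample_type %in% c("prenatal", "foetal"))
  log <- bind_rows(log, tibble(sample_id = pre$sample_id, rule = "prenatal_or_foetal"))
  kept <- samples %>% filter(!.data$sample_type %in% c("prenatal", "foetal"))
  # (i) one sample per family, chosen uniformly at random
  kept <- kept %>%
    group_by(.data$family_id) %>%
    mutate(.keep_fam = row_number() == sample.int(n(), 1L)) %>%
    ungroup()
  log <- bind_rows(log, tibble(sample_id = kept$sample_id[!kept$.keep_fam],
                               rule = "one_per_family"))
  kept <- kept %>% filter(.data$.keep_fam) %>% select(-".keep_fam")
  # (ii) one partner per consanguineous couple (links may already be broken
  # by the family rule)
  drop <- character()
  remaining <- kept$sample_id
  for (i in seq_len(nrow(kept))) {
    sid <- kept$sample_id[i]
    p <- kept$partner_id[i]
    if (!is.na(p) && sid %in% remaining && p %in% remaining) {
      pair <- c(sid, p)
      loser <- pair[sample.int(2L, 1L)]
      drop <- c(drop, loser)
      remaining <- setdiff(remaining, loser)
    }
  }
  log <- bind_rows(log, tibble(sample_id = drop, rule = "one_per_couple"))
  kept <- kept %>% filter(!.data$sample_id %in% drop)
  attr(kept, "exclusion_log") <- log
  kept
}

#' Exclusion log of a filtered sample set
#'
#' @param samples Output of [apply_exclusions()].
#' @return Tibble with `sample_id` and the `rule` that excluded it.
#' @export
exclusion_log <- function(samples) {
  attr(samples, "exclusion_log") %||% tibble(sample_id = character(), rule = character())
}

# Largest-remainder (Hamilton) apportionment of `total` over `weights`,
# deterministic: remainder ties break by stratum order.
largest_remainder <- function(total, weights) {
  if (total == 0 || sum(weights) == 0) return(rep(0L, length(weights)))
  q <- total * weights / sum(weights)
  base <- floor(q)
  left <- as.integer(round(total - sum(base)))
  extra <- integer(length(weights))
  if (left > 0) {
    ord <- order(-(q - base), seq_along(q))
    extra[ord[seq_len(left)]] <- 1L
  }
  as.integer(base + extra)
}

# Apportion with per-stratum caps: deficits from saturated strata are
# redistributed proportionally over unsaturated ones, iterated to fixpoint.
apportion_capped <- function(total, weights, caps) {
  target <- rep(0L, length(weights))
  open <- rep(TRUE, length(weights))
  remaining <- total
  repeat {
    add <- largest_remainder(remaining, ifelse(open, weights, 0))
    target <- pmin(target + add, caps)
    sat <- target >= caps
    remaining <- total - sum(target)
    if (remaining == 0 || !any(open & !sat)) break
    open <- open & !sat
  }
  target
}

#' Census-stratified resampling of a cohort
#'
#' Draws a population-representative subset: per-municipality targets are the
#' largest-remainder apportionment of `target_n` by census population
#' proportions, capped by per-stratum availability with the deficit
#' redistributed proportionally across unsaturated strata; sampling is
#' without replacement within strata and deterministic given the seed.
#'
#' @param samples Sample metadata (exclusions already applied), with a
#'   `municipality` column.
#' @param census Tibble with `code` and `population` (see
#'   [generate_census_table()]).
#' @param target_n Desired subset size (must not exceed the available
#'   samples).
#' @param seed Integer seed.
#' @return List with `samples` (the subset tibble) and `plan` (a
#'   `resample_plan` tibble: per-municipality census population, proportion,
#'   availability, target and attained counts, with `target_n` and `seed` as
#'   attributes). `tidy()` on the plan returns it as a plain tibble.
#' @export
stratified_resample <- function(samples, census, target_n, seed) {
  stopifnot("municipality" %in% names(samples))
  target_n <- as.integer(target_n)
  if (target_n > nrow(samples)) {
    abort(paste0("target_n exceeds available samples by ", target_n - nrow(samples)))
  }
  avail <- samples %>% count(municipality = .data$municipality, name = "available")
  plan <- census %>%
    select(municipality = "code", population = "population") %>%
    left_join(avail, by = "municipality") %>%
    mutate(
      available = tidyr::replace_na(.data$available, 0L),
      proportion = .data$population / sum(.data$population)
    )
  extra <- setdiff(avail$municipality, plan$municipality)
  if (length(extra)) {
    abort(paste0("samples from municipalities absent from the census: ",
                 paste(extra, collapse = ", ")))
  }
  plan$target <- apportion_capped(target_n, plan$proportion, plan$available)
  if (sum(plan$target) < target_n) {
    abort(paste0("target_n exceeds available samples by ", target_n - sum(plan$target)))
  }
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  subset <- purrr::map_dfr(seq_len(nrow(plan)), function(i) {
    pool <- samples %>% filter(.data$municipality == plan$municipality[i])
    take <- plan$target[i]
    if (take == 0L) return(pool[0, ])
    pool[sort(sample.int(nrow(pool), take)), ]
  })
  plan$attained <- plan$target
  plan <- structure(plan, class = c("resample_plan", class(plan)),
                    target_n = target_n, seed = seed)
  list(samples = subset, plan = plan)
}

#' @exportS3Method generics::tidy
tidy.resample_plan <- function(x, ...) {
  as_tibble(unclass(x))
}
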