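#' Regional burden tallies
#'
#' Counts transitions/transversions, rare/common variants and
#' non-synonymous/synonymous variants per group for one mtDNA region, the
#' whole genome (`"overall"`), or the whole genome on distinct variants
#' (`"overall_unique"`). `occurrence` mode counts every variant observation
#' across subjects; `unique` mode counts each distinct (position, alt) at most
#' once per group. Non-synonymous/synonymous counts cover protein-coding
#' effects only, and rare/common counts exclude variants of unknown population
#' frequency.
#'
#' Variants named in `exclusions` (default: the primary LHON mutation
#' m.11778G>A, carried by every patient by design) are left out of the
#' complex I, overall and overall-unique tallies, so a mutation used to define
#' the patient group cannot masquerade as an association signal. The exclusion
#' removes the variant from all six counters; for m.11778G>A only the
#' transition, non-synonymous and (if its frequency is known) rare/common
#' counters are affected in practice.
#'
#' @param cohort An annotated `mt_cohort` (see [annotate_cohort()]).
#' @param region One of the seven regions, `"overall"`, or `"overall_unique"`.
#' @param mode `"occurrence"` or `"unique"`; `"overall_unique"` forces
#'   `"unique"`.
#' @param exclusions Character vector of m.-notation variant keys.
#' @return Tibble with one row per group: `region`, `group`, `mode`, `ts`,
#'   `tv`, `rare`, `common`, `unknown_rarity`, `ns`, `s`, `n_variants`.
#' @export
tally_burden <- function(cohort, region, mode = c("occurrence", "unique"),
                         exclusions = "m.11778G>A") {
  .assert_annotated(cohort)
  mode <- match.arg(mode)
  valid <- c(.mt_regions, "overall", "overall_unique")
  if (!region %in% valid) stop("unknown region: ", region)
  if (region == "overall_unique") mode <- "unique"

  v <- dplyr::left_join(cohort$variants,
                        cohort$subjects[, c("subject_id", "group")],
                        by = "subject_id")
  v$key <- variant_key(v$position, v$ref, v$alt)

  if (region %in% c("complexI", "overall", "overall_unique")) {
    v <- v[!v$key %in% exclusions, ]
  }
  if (!region %in% c("overall", "overall_unique")) {
    v <- v[v$region == region, ]
  }
  if (mode == "unique") {
    v <- dplyr::distinct(v, .data$group, .data$position, .data$alt,
                         .keep_all = TRUE)
  }

  rows <- lapply(c("patient", "control"), function(g) {
    vg <- v[v$group == g, ]
    tibble::tibble(
      region = region, group = g, mode = mode,
      ts = sum(vg$substitution == "transition"),
      tv = sum(vg$substitution == "transversion"),
      rare = sum(vg$rarity == "rare"),
      common = sum(vg$rarity == "common"),
      unknown_rarity = sum(vg$rarity == "unknown"),
      ns = sum(vg$category == "non-synonymous"),
      s = sum(vg$category == "synonymous"),
      n_variants = nrow(vg)
    )
  })
  dplyr::bind_rows(rows)
}

#' Transition/transversion ratio
#'
#' @param ts,tv Counts.
#' @return `ts/tv`, or `NA` when `tv` is zero (rendered "n/a" in reports).
#' @export
#' @examples
#' ts_tv_ratio(1189, 34)  # 34.97
ts_tv_ratio <- function(ts, tv) {
  ifelse(tv > 0, ts / tv, NA_real_)
}

#' Compare a burden metric between groups
#'
#' Builds the 2x2 table with the metric counts as exposure rows (patients'
#' counts in the first column, controls' in the second) and delegates to the
#' exact association statistics; the Haldane-correction flag is propagated.
#' When an entire exposure row is empty in both groups (e.g. zero
#' transversions in both, as for tRNA variants), there is no contrast to test
#' and an all-`NA` result row is returned.
#'
#' @param burden Two-row tibble from [tally_burden()] (one row per group,
#'   same region and mode).
#' @param metric `"ts_vs_tv"`, `"rare_vs_common"`, or `"ns_vs_s"`.
#' @return One-row tibble: region, metric, the four cells, `p_value`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `haldane_applied`.
#' @export
compare_burden <- function(burden,
                           metric = c("ts_vs_tv", "rare_vs_common", "ns_vs_s")) {
  metric <- match.arg(metric)
  stopifnot(nrow(burden) == 2)
  if (length(unique(burden$region)) != 1 || length(unique(burden$mode)) != 1) {
    stop("group burdens must share region and mode")
  }
  pat <- burden[burden$group == "patient", ]
  con <- burden[burden$group == "control", ]
  stopifnot(nrow(pat) == 1, nrow(con) == 1)
  cols <- switch(metric,
    ts_vs_tv = c("ts", "tv"),
    rare_vs_common = c("rare", "common"),
    ns_vs_s = c("ns", "s")
  )
  a <- pat[[cols[1]]]; b <- pat[[cols[2]]]
  c_ <- con[[cols[1]]]; d <- con[[cols[2]]]
  base <- tibble::tibble(region = pat$region, mode = pat$mode, metric = metric)
  if ((a + c_) == 0 || (b + d) == 0) {
    return(dplyr::bind_cols(base, tibble::tibble(
      a = a, b = b, c = c_, d = d,
      p_value = NA_real_, odds_ratio = NA_real_,
      ci_low = NA_real_, ci_high = NA_real_, haldane_applied = NA
    )))
  }
  dplyr::bind_cols(base, association_2x2(a, b, c_, d))
}

#' Carrier-level 2x2 table
#'
#' A subject is a carrier when at least one of its variants passes every
#' active filter (region, rarity, pathogenicity-score threshold). Cells are
#' `a` = patient carriers, `b` = patient non-carriers, `c` = control carriers,
#' `d` = control non-carriers.
#'
#' @param cohort An annotated `mt_cohort`.
#' @param region Optional region filter (one of the seven regions).
#' @param rarity Optional rarity filter (`"rare"` or `"common"`).
#' @param score_gt Optional strict lower bound on the pathogenicity score;
#'   requires scores to be attached.
#' @param exclusions m.-notation keys never counted (default m.11778G>A).
#' @return List with `a`, `b`, `c`, `d` and the carrier subject ids.
#' @export
carrier_table <- function(cohort, region = NULL, rarity = NULL,
                          score_gt = NULL, exclusions = "m.11778G>A") {
  .assert_annotated(cohort)
  v <- cohort$variants
  v$key <- variant_key(v$position, v$ref, v$alt)
  v <- v[!v$key %in% exclusions, ]
  if (!is.null(region)) {
    if (!region %in% .mt_regions) stop("unknown region: ", region)
    v <- v[v$region == region, ]
  }
  if (!is.null(rarity)) v <- v[v$rarity == rarity, ]
  if (!is.null(score_gt)) {
    if (!"score" %in% names(v)) {
      stop("score filter requested but no scores attached to the cohort")
    }
    v <- v[!is.na(v$score) & v$score > score_gt, ]
  }
  carriers <- unique(v$subject_id)
  s <- cohort$subjects
  a <- sum(s$group == "patient" & s$subject_id %in% carriers)
  c_ <- sum(s$group == "control" & s$subject_id %in% carriers)
  list(a = a, b = n_patients(cohort) - a,
       c = c_, d = n_controls(cohort) - c_,
       carriers = carriers)
}

#' Rare/common variant shares per region
#'
#' Shares are counts divided by (rare + common) per region per group;
#' unknown-rarity variants are reported separately and excluded from the
#' denominator. Regions with an empty denominator return `NA` shares.
#'
#' @param cohort An annotated `mt_cohort`.
#' @param mode `"occurrence"` (default, consistent with the Fisher inputs of
#'   the regional rare-variant comparison) or `"unique"`.
#' @param exclusions m.-notation keys excluded from complex I (see
#'   [tally_burden()]).
#' @return Tibble per region per group: `rare`, `common`, `unknown_rarity`,
#'   `share_rare`, `share_common`.
#' @export
rarity_spectrum <- function(cohort, mode = c("occurrence", "unique"),
                            exclusions = "m.11778G>A") {
  mode <- match.arg(mode)
  rows <- lapply(.mt_regions, function(r) {
    tally_burden(cohort, r, mode, exclusions)
  })
  b <- dplyr::bind_rows(rows)
  denom <- b$rare + b$common
  b$share_rare <- ifelse(denom > 0, b$rare / denom, NA_real_)
  b$share_common <- ifelse(denom > 0, b$common / denom, NA_real_)
  b[, c("region", "group", "mode", "rare", "common", "unknown_rarity",
        "share_rare", "share_common")]
}
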