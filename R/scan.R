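#' Per-variant case-control association scan
#'
#' For every distinct (position, alt) observed in the cohort, builds the
#' carrier 2x2 table (subjects carrying the variant vs not, by group) and
#' computes the two-sided Fisher exact p-value, Haldane-corrected odds ratio
#' and Woolf confidence interval. Variants named in `exclusions` (default the
#' primary mutation, which defines the patient group) are skipped.
#'
#' @param cohort An annotated `mt_cohort`.
#' @param exclusions m.-notation keys to skip.
#' @param min_carriers Minimum total carrier count for a variant to be tested.
#' @return Tibble sorted by p-value: variant key, locus, region, effect,
#'   carrier frequencies per group (percent) and association statistics.
#' @export
snv_scan <- function(cohort, exclusions = "m.11778G>A", min_carriers = 1L) {
  .assert_annotated(cohort)
  v <- dplyr::left_join(cohort$variants,
                        cohort$subjects[, c("subject_id", "group")],
                        by = "subject_id")
  v$key <- variant_key(v$position, v$ref, v$alt)
  v <- v[!v$key %in% exclusions, ]
  np <- n_patients(cohort)
  nc <- n_controls(cohort)

  counts <- dplyr::summarise(
    dplyr::group_by(v, .data$key, .data$position, .data$alt, .data$locus,
                    .data$region, .data$category, .data$protein_change),
    carriers_pat = sum(.data$group == "patient"),
    carriers_con = sum(.data$group == "control"),
    .groups = "drop"
  )
  counts <- counts[counts$carriers_pat + counts$carriers_con >= min_carriers, ]
  if (nrow(counts) == 0) {
    return(tibble::tibble())
  }
  stats_rows <- lapply(seq_len(nrow(counts)), function(i) {
    association_2x2(counts$carriers_pat[i], np - counts$carriers_pat[i],
                    counts$carriers_con[i], nc - counts$carriers_con[i])
  })
  stats_tbl <- dplyr::bind_rows(stats_rows)
  out <- dplyr::bind_cols(
    counts,
    tibble::tibble(
      freq_pat = 100 * counts$carriers_pat / np,
      freq_con = 100 * counts$carriers_con / nc
    ),
    stats_tbl[, c("p_value", "odds_ratio", "ci_low", "ci_high",
                  "haldane_applied")]
  )
  dplyr::arrange(out, .data$p_value, .data$position)
}

#' Haplogroup distribution table with association statistics
#'
#' Tallies reporting-level haplogroup calls per group and computes, for each
#' label, the Fisher/OR/CI comparison of its prevalence between groups.
#'
#' @param cohort An `mt_cohort` with haplogroups assigned
#'   (see [assign_haplogroups()]).
#' @return Tibble: `haplogroup`, per-group counts and percent frequencies,
#'   `p_value`, `odds_ratio`, `ci_low`, `ci_high`, `haldane_applied`.
#' @export
haplogroup_distribution <- function(cohort) {
  s <- cohort$subjects
  if (!"haplogroup_report" %in% names(s) || all(is.na(s$haplogroup_report))) {
    stop("assign haplogroups first; run assign_haplogroups()")
  }
  np <- n_patients(cohort)
  nc <- n_controls(cohort)
  labels <- sort(unique(s$haplogroup_report))
  rows <- lapply(labels, function(h) {
    a <- sum(s$group == "patient" & s$haplogroup_report == h)
    c_ <- sum(s$group == "control" & s$haplogroup_report == h)
    st <- association_2x2(a, np - a, c_, nc - c_)
    tibble::tibble(
      haplogroup = h, n_pat = a, n_con = c_,
      freq_pat = 100 * a / np, freq_con = 100 * c_ / nc,
      p_value = st$p_value, odds_ratio = st$odds_ratio,
      ci_low = st$ci_low, ci_high = st$ci_high,
      haldane_applied = st$haldane_applied
    )
  })
  dplyr::bind_rows(rows)
}

#' Regional burden comparison tables
#'
#' Assembles the transition/transversion, rare-variant and
#' non-synonymous/synonymous comparison tables over the seven regions plus
#' the overall and overall-unique categories, mirroring the layout of
#' published regional-burden tables.
#'
#' @param cohort An annotated `mt_cohort`.
#' @param exclusions m.-notation keys excluded from complex I and the overall
#'   categories (see [tally_burden()]).
#' @return Named list of tibbles: `tstv`, `rare`, `nss`.
#' @export
burden_tables <- function(cohort, exclusions = "m.11778G>A") {
  .assert_annotated(cohort)
  regions <- c(.mt_regions, "overall", "overall_unique")
  tstv <- list(); rare <- list(); nss <- list()
  for (r in regions) {
    b <- tally_burden(cohort, r, "occurrence", exclusions)
    pat <- b[b$group == "patient", ]
    con <- b[b$group == "control", ]
    cmp_ts <- compare_burden(b, "ts_vs_tv")
    tstv[[r]] <- tibble::tibble(
      region = r,
      ts_pat = pat$ts, tv_pat = pat$tv, ratio_pat = ts_tv_ratio(pat$ts, pat$tv),
      ts_con = con$ts, tv_con = con$tv, ratio_con = ts_tv_ratio(con$ts, con$tv),
      p_value = cmp_ts$p_value, odds_ratio = cmp_ts$odds_ratio,
      ci_low = cmp_ts$ci_low, ci_high = cmp_ts$ci_high,
      haldane_applied = cmp_ts$haldane_applied
    )
    cmp_rare <- compare_burden(b, "rare_vs_common")
    rare[[r]] <- tibble::tibble(
      region = r,
      rare_pat = pat$rare, common_pat = pat$common,
      rare_con = con$rare, common_con = con$common,
      unknown_pat = pat$unknown_rarity, unknown_con = con$unknown_rarity,
      p_value = cmp_rare$p_value, odds_ratio = cmp_rare$odds_ratio,
      ci_low = cmp_rare$ci_low, ci_high = cmp_rare$ci_high,
      haldane_applied = cmp_rare$haldane_applied
    )
    if (r %in% c(.coding_regions, "overall", "overall_unique")) {
      cmp_nss <- compare_burden(b, "ns_vs_s")
      nss[[r]] <- tibble::tibble(
        region = r,
        ns_pat = pat$ns, s_pat = pat$s,
        ratio_pat = ifelse(pat$s > 0, pat$ns / pat$s, NA_real_),
        ns_con = con$ns, s_con = con$s,
        ratio_con = ifelse(con$s > 0, con$ns / con$s, NA_real_),
        p_value = cmp_nss$p_value, odds_ratio = cmp_nss$odds_ratio,
        ci_low = cmp_nss$ci_low, ci_high = cmp_nss$ci_high,
        haldane_applied = cmp_nss$haldane_applied
      )
    }
  }
  list(tstv = dplyr::bind_rows(tstv),
       rare = dplyr::bind_rows(rare),
       nss = dplyr::bind_rows(nss))
}
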