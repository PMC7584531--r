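#' Per-subject pathogenicity variant loads
#'
#' The total variant load of a subject is the sum of pathogenicity scores over
#' its non-synonymous variants; the threshold load sums only scores strictly
#' above the threshold. The primary mutation (default m.11778G>A) is excluded
#' from both. Non-synonymous variants missing from the score table are skipped
#' with a warning by default (`missing_score = "skip"`), or raise an error
#' (`"fail"`).
#'
#' @param cohort An annotated `mt_cohort` with scores attached (see
#'   [annotate_cohort()]).
#' @param threshold Strict score threshold for the second load. Default 0.5.
#' @param exclusions m.-notation keys excluded from the sums.
#' @param missing_score `"skip"` (default) or `"fail"`.
#' @return Tibble per subject: `subject_id`, `group`, `total_load`,
#'   `threshold_load`, `n_ns` (scored non-synonymous variants),
#'   `n_unscored` (skipped for lack of a score).
#' @export
compute_loads <- function(cohort, threshold = 0.5, exclusions = "m.11778G>A",
                          missing_score = c("skip", "fail")) {
  .assert_annotated(cohort)
  missing_score <- match.arg(missing_score)
  v <- cohort$variants
  if (!"score" %in% names(v)) {
    stop("no scores attached to the cohort; pass a score table to annotate_cohort()")
  }
  v$key <- variant_key(v$position, v$ref, v$alt)
  ns <- v[v$category == "non-synonymous" & !v$key %in% exclusions, ]
  unscored <- is.na(ns$score)
  if (any(unscored)) {
    msg <- sprintf("%d non-synonymous variant observation(s) lack a score (e.g. %s)",
                   sum(unscored), ns$key[unscored][1])
    if (missing_score == "fail") stop(msg)
    warning(msg, "; skipped")
  }
  scored <- ns[!unscored, ]
  per <- dplyr::summarise(
    dplyr::group_by(scored, .data$subject_id),
    total_load = sum(.data$score),
    threshold_load = sum(.data$score[.data$score > threshold]),
    n_ns = dplyr::n(),
    .groups = "drop"
  )
  un <- dplyr::count(ns[unscored, , drop = FALSE], .data$subject_id,
                     name = "n_unscored")
  out <- dplyr::left_join(cohort$subjects[, c("subject_id", "group")], per,
                          by = "subject_id")
  out <- dplyr::left_join(out, un, by = "subject_id")
  out$total_load[is.na(out$total_load)] <- 0
  out$threshold_load[is.na(out$threshold_load)] <- 0
  out$n_ns[is.na(out$n_ns)] <- 0L
  out$n_unscored[is.na(out$n_unscored)] <- 0L
  out
}

#' Compare variant loads between groups
#'
#' Reports group means and standard deviations of the total and threshold
#' loads, compares them with two-sample t-tests (pooled variance by default),
#' and builds the carrier 2x2 for subjects with at least one variant scoring
#' above the threshold.
#'
#' @param cohort An annotated, scored `mt_cohort` with at least two subjects
#'   per group.
#' @inheritParams compute_loads
#' @param var_equal Pooled-variance t-test if `TRUE` (default), Welch
#'   otherwise.
#' @return List with `loads` (per-subject tibble), `summary` (per-group,
#'   per-load means/sds), `t_total`, `t_threshold` (t-test results), and
#'   `carriers` (carrier 2x2 with association statistics).
#' @export
compare_loads <- function(cohort, threshold = 0.5, exclusions = "m.11778G>A",
                          var_equal = TRUE, missing_score = c("skip", "fail")) {
  missing_score <- match.arg(missing_score)
  if (n_patients(cohort) < 2 || n_controls(cohort) < 2) {
    stop("need at least two subjects per group")
  }
  loads <- compute_loads(cohort, threshold, exclusions, missing_score)
  summary <- dplyr::summarise(
    dplyr::group_by(loads, .data$group),
    n = dplyr::n(),
    mean_total = mean(.data$total_load), sd_total = stats::sd(.data$total_load),
    mean_threshold = mean(.data$threshold_load),
    sd_threshold = stats::sd(.data$threshold_load),
    .groups = "drop"
  )
  pat <- summary[summary$group == "patient", ]
  con <- summary[summary$group == "control", ]
  t_total <- pooled_t_test(pat$mean_total, pat$sd_total, pat$n,
                           con$mean_total, con$sd_total, con$n, var_equal)
  t_threshold <- pooled_t_test(pat$mean_threshold, pat$sd_threshold, pat$n,
                               con$mean_threshold, con$sd_threshold, con$n,
                               var_equal)
  ct <- carrier_table(cohort, score_gt = threshold, exclusions = exclusions)
  carriers <- association_2x2(ct$a, ct$b, ct$c, ct$d)
  list(loads = loads, summary = summary,
       t_total = t_total, t_threshold = t_threshold,
       carriers = carriers)
}
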