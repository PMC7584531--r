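#' Construct a case-control mtDNA cohort
#'
#' A cohort couples a subject table (id, group, optional haplogroup call) with
#' a long-format variant table (one row per subject per variant). Variants are
#' keyed by (position, alt) within a subject; duplicates are an error.
#'
#' @param subjects Tibble/data.frame with columns `subject_id`, `group`
#'   (`"patient"` or `"control"`).
#' @param variants Tibble/data.frame with columns `subject_id`, `position`,
#'   `ref`, `alt`, `heteroplasmy` (percent in (0, 100]).
#' @return Object of class `mt_cohort`.
#' @export
mt_cohort <- function(subjects, variants) {
  subjects <- tibble::as_tibble(subjects)
  variants <- tibble::as_tibble(variants)
  stopifnot(all(c("subject_id", "group") %in% names(subjects)),
            all(c("subject_id", "position", "ref", "alt", "heteroplasmy")
                %in% names(variants)))
  if (!all(subjects$group %in% c("patient", "control"))) {
    stop("group must be 'patient' or 'control'")
  }
  if (anyDuplicated(subjects$subject_id)) stop("duplicate subject ids")
  orphan <- setdiff(variants$subject_id, subjects$subject_id)
  if (length(orphan) > 0) {
    stop("variants for unknown subject(s): ", paste(head(orphan, 3), collapse = ", "))
  }
  dup <- duplicated(variants[, c("subject_id", "position", "alt")])
  if (any(dup)) {
    stop("duplicate (subject, position, alt) variant entries, e.g. subject ",
         variants$subject_id[dup][1], " position ", variants$position[dup][1])
  }
  h <- variants$heteroplasmy
  if (any(!is.na(h) & (h <= 0 | h > 100))) {
    stop("heteroplasmy fraction must lie in (0, 100]")
  }
  variants$position <- as.integer(variants$position)
  if (!"haplogroup" %in% names(subjects)) subjects$haplogroup <- NA_character_
  structure(list(subjects = subjects, variants = variants), class = "mt_cohort")
}

#' @export
print.mt_cohort <- function(x, ...) {
  cat(sprintf("mt cohort: %d patients, %d controls, %d variant observations\n",
              n_patients(x), n_controls(x), nrow(x$variants)))
  invisible(x)
}

#' Group sizes of a cohort
#' @param cohort An `mt_cohort`.
#' @return Integer count.
#' @export
n_patients <- function(cohort) sum(cohort$subjects$group == "patient")

#' @rdname n_patients
#' @export
n_controls <- function(cohort) sum(cohort$subjects$group == "control")

#' Heteroplasmy status of a variant
#'
#' A variant is called heteroplasmic when its mutant-allele fraction lies below
#' the homoplasmy threshold. The default of 95% is a caller convention: the
#' highest fraction a typical pipeline still reports as heteroplasmic in this
#' kind of data is around 92%.
#'
#' @param fraction Numeric vector of mutant-allele percentages in (0, 100].
#' @param homoplasmy_threshold Percent at or above which a call is homoplasmic.
#' @return Character vector `"homoplasmic"`/`"heteroplasmic"`.
#' @export
#' @examples
#' heteroplasmy_status(c(92, 100, 95))
heteroplasmy_status <- function(fraction, homoplasmy_threshold = 95) {
  if (any(is.na(fraction) | fraction <= 0 | fraction > 100)) {
    stop("heteroplasmy fraction must lie in (0, 100]")
  }
  ifelse(fraction < homoplasmy_threshold, "heteroplasmic", "homoplasmic")
}

#' Annotate variant rarity from a population-frequency table
#'
#' Variants at or below the cutoff are `rare`, above it `common`; variants
#' absent from the table are `unknown` and are excluded from rare/common
#' tallies downstream (they are reported separately rather than assumed rare).
#' Re-annotation is idempotent.
#'
#' @param cohort An `mt_cohort` (annotated or not).
#' @param frequencies Frequency table from [read_frequency_table()] (columns
#'   `position`, `alt`, `percent`).
#' @param rare_cutoff Percent; the comparison is inclusive (<=). Default 0.5.
#' @return The cohort with `population_frequency` and `rarity` columns set on
#'   its variant table.
#' @export
annotate_frequency <- function(cohort, frequencies, rare_cutoff = 0.5) {
  stopifnot(inherits(cohort, "mt_cohort"), rare_cutoff > 0)
  freq <- .as_frequency_table(frequencies)
  if (any(freq$percent < 0 | freq$percent > 100)) {
    stop("population frequencies must lie in [0, 100]")
  }
  v <- cohort$variants
  v$population_frequency <- NULL
  v$rarity <- NULL
  v <- dplyr::left_join(v, freq, by = c("position", "alt"))
  v <- dplyr::rename(v, population_frequency = "percent")
  v$rarity <- dplyr::case_when(
    is.na(v$population_frequency) ~ "unknown",
    v$population_frequency <= rare_cutoff ~ "rare",
    TRUE ~ "common"
  )
  cohort$variants <- v
  cohort
}

.as_frequency_table <- function(frequencies) {
  freq <- tibble::as_tibble(frequencies)
  if ("variant" %in% names(freq) && !"position" %in% names(freq)) {
    parsed <- parse_variant_key(freq$variant)
    freq$position <- parsed$position
    freq$alt <- parsed$alt
  }
  stopifnot(all(c("position", "alt", "percent") %in% names(freq)))
  freq <- dplyr::distinct(freq[, c("position", "alt", "percent")],
                          .data$position, .data$alt, .keep_all = TRUE)
  freq$position <- as.integer(freq$position)
  freq
}

#' Flag variants previously reported to associate with a disease
#'
#' @param cohort An `mt_cohort`.
#' @param association_list Tibble with columns `variant` (m.-notation) and
#'   `annotation`, e.g. from [read_association_list()]. An empty list clears
#'   all flags.
#' @return Cohort with a `reported_association` column on its variant table;
#'   non-matching variants carry `NA`.
#' @export
flag_reported <- function(cohort, association_list) {
  stopifnot(inherits(cohort, "mt_cohort"))
  v <- cohort$variants
  v$reported_association <- NULL
  assoc <- tibble::as_tibble(association_list)
  if (nrow(assoc) == 0) {
    v$reported_association <- NA_character_
  } else {
    stopifnot(all(c("variant", "annotation") %in% names(assoc)))
    parsed <- parse_variant_key(assoc$variant)
    assoc <- tibble::tibble(position = parsed$position, alt = parsed$alt,
                            reported_association = assoc$annotation)
    v <- dplyr::left_join(v, assoc, by = c("position", "alt"))
  }
  cohort$variants <- v
  cohort
}

#' Fully annotate a cohort against a gene model
#'
#' Runs, in order: reference-checked effect annotation (locus, region,
#' transition/transversion, synonymous/non-synonymous with protein change),
#' population-frequency rarity classing, reported-association flagging,
#' pathogenicity-score lookup, and heteroplasmy status.
#'
#' @param cohort An `mt_cohort`.
#' @param model An `mt_gene_model` (default: packaged model).
#' @param frequencies Optional frequency table (tibble or path).
#' @param scores Optional score table (tibble or path, see [read_score_table()]).
#' @param reported Optional association list (tibble or path).
#' @param rare_cutoff Rarity cutoff in percent, inclusive. Default 0.5.
#' @param homoplasmy_threshold Percent, default 95.
#' @return The cohort with a fully annotated variant table.
#' @export
annotate_cohort <- function(cohort, model = mt_gene_model(),
                            frequencies = NULL, scores = NULL, reported = NULL,
                            rare_cutoff = 0.5, homoplasmy_threshold = 95) {
  stopifnot(inherits(cohort, "mt_cohort"))
  v <- cohort$variants
  keep <- c("subject_id", "position", "ref", "alt", "heteroplasmy")
  v <- v[, intersect(keep, names(v))]

  uniq <- dplyr::distinct(v, .data$position, .data$ref, .data$alt)
  eff <- annotate_effects(uniq$position, uniq$ref, uniq$alt, model)
  eff$substitution <- classify_substitution(eff$ref, eff$alt)
  v <- dplyr::left_join(v, eff, by = c("position", "ref", "alt"))
  v$status <- heteroplasmy_status(v$heteroplasmy, homoplasmy_threshold)
  cohort$variants <- v

  if (!is.null(frequencies)) {
    if (is.character(frequencies)) frequencies <- read_frequency_table(frequencies)
    cohort <- annotate_frequency(cohort, frequencies, rare_cutoff)
  } else {
    cohort$variants$population_frequency <- NA_real_
    cohort$variants$rarity <- "unknown"
  }
  if (!is.null(reported)) {
    if (is.character(reported)) reported <- read_association_list(reported)
    cohort <- flag_reported(cohort, reported)
  }
  if (!is.null(scores)) {
    if (is.character(scores)) scores <- read_score_table(scores)
    cohort <- .attach_scores(cohort, scores)
  }
  attr(cohort, "annotated") <- TRUE
  cohort
}

# score lookup by nucleotide key first, then by amino-acid change key
.attach_scores <- function(cohort, scores) {
  sc <- tibble::as_tibble(scores)
  stopifnot("score" %in% names(sc))
  if (any(!is.na(sc$score) & (sc$score < 0 | sc$score > 1))) {
    stop("pathogenicity scores must lie in [0, 1]")
  }
  v <- cohort$variants
  v$score <- NULL
  v$key <- variant_key(v$position, v$ref, v$alt)
  by_nt <- if ("variant" %in% names(sc)) {
    setNames(sc$score, sc$variant)
  } else c()
  by_aa <- if ("protein_change" %in% names(sc)) {
    ok <- !is.na(sc$protein_change) & nzchar(sc$protein_change)
    setNames(sc$score[ok], paste0(sc$protein_change[ok]))
  } else c()
  v$score <- rep(NA_real_, nrow(v))
  if (length(by_nt) > 0) v$score <- unname(by_nt[v$key])
  if (length(by_aa) > 0 && "protein_change" %in% names(v)) {
    miss <- is.na(v$score) & !is.na(v$protein_change) & nzchar(v$protein_change)
    v$score[miss] <- unname(by_aa[v$protein_change[miss]])
  }
  v$key <- NULL
  cohort$variants <- v
  cohort
}

#' Is the cohort fully annotated?
#' @param cohort An `mt_cohort`.
#' @return Logical.
#' @export
is_annotated <- function(cohort) isTRUE(attr(cohort, "annotated"))

.assert_annotated <- function(cohort) {
  if (!is_annotated(cohort)) {
    stop("cohort must be annotated first; run annotate_cohort()")
  }
  miss <- is.na(cohort$variants$category)
  if (any(miss)) {
    i <- which(miss)[1]
    stop("unannotated variant: subject ", cohort$variants$subject_id[i],
         " position ", cohort$variants$position[i])
  }
  invisible(cohort)
}
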