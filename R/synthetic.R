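#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study conditions of a male LHON m.11778G>A
#' case-control cohort: 47 patients (every one carrying the primary mutation
#' m.11778G>A, homoplasmic except for a ~4/47 chance of 70-95% heteroplasmy)
#' versus 42 controls; per-group haplogroup frequencies matching the reported
#' 12-haplogroup distribution; per-region expected variant counts per subject
#' derived from the reported regional occurrence totals; transition
#' probability 0.97 (overall Ts/Tv around 33); non-synonymous probability 0.40
#' for coding variants; pathogenicity scores drawn from Beta(2, 4).
#' Per-region rare-variant shares follow the direction and, where printed, the
#' magnitude of the reported regional differences (complex IV: 19% of patient
#' vs 34% of control variant occurrences rare).
#'
#' @param n_patients,n_controls Group sizes.
#' @param haplogroup_freqs List with `patient` and `control` named probability
#'   vectors over haplogroup labels of the marker tree.
#' @param marker_fidelity Probability that a subject carries its haplogroup's
#'   complete root-to-node marker set; otherwise one random marker is dropped.
#' @param region_rates Data frame with columns `region`, `rate_patient`,
#'   `rate_control` (expected variants per subject, Poisson) and
#'   `rare_share_patient`, `rare_share_control` (probability a drawn variant
#'   is population-rare).
#' @param ts_prob Probability a drawn substitution is a transition.
#' @param ns_prob Probability a drawn coding substitution is non-synonymous.
#' @param score_shape Beta shape parameters for non-synonymous scores.
#' @param het_prob,het_range Probability that a patient's primary mutation is
#'   heteroplasmic, and the uniform range (percent) of the heteroplasmy level.
#' @param force_primary Plant m.11778G>A in every patient (`TRUE` for the
#'   study-emulating configuration; set `FALSE` for null cohorts).
#' @param seed Integer seed; one pseudo-random stream per cohort.
#' @return List of class `mt_sim_config`.
#' @export
simulation_config <- function(n_patients = 47L,
                              n_controls = 42L,
                              haplogroup_freqs = default_haplogroup_freqs(),
                              marker_fidelity = 1.0,
                              region_rates = default_region_rates(),
                              ts_prob = 0.97,
                              ns_prob = 0.40,
                              score_shape = c(2, 4),
                              het_prob = 4 / 47,
                              het_range = c(70, 95),
                              force_primary = TRUE,
                              seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
    haplogroup_freqs = haplogroup_freqs, marker_fidelity = marker_fidelity,
    region_rates = tibble::as_tibble(region_rates),
    ts_prob = ts_prob, ns_prob = ns_prob, score_shape = score_shape,
    het_prob = het_prob, het_range = het_range,
    force_primary = isTRUE(force_primary), seed = as.integer(seed)
  )
  for (g in c("patient", "control")) {
    p <- cfg$haplogroup_freqs[[g]]
    if (is.null(p) || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("haplogroup_freqs$", g, " must be a probability vector summing to 1")
    }
  }
  rr <- cfg$region_rates
  stopifnot(all(c("region", "rate_patient", "rate_control",
                  "rare_share_patient", "rare_share_control") %in% names(rr)))
  if (!setequal(rr$region, .mt_regions)) stop("region_rates must cover the seven regions")
  if (any(rr$rate_patient < 0 | rr$rate_control < 0)) stop("rates must be >= 0")
  if (any(rr[, 4:5] < 0 | rr[, 4:5] > 1)) stop("rare shares must lie in [0,1]")
  if (cfg$marker_fidelity < 0 || cfg$marker_fidelity > 1) stop("marker_fidelity in [0,1]")
  class(cfg) <- "mt_sim_config"
  cfg
}

#' @rdname simulation_config
#' @export
default_haplogroup_freqs <- function() {
  list(
    patient = c(B = 1, H = 15, HV = 1, I = 2, J = 5, K = 5, N = 2, T = 3,
                U = 9, V = 1, W = 2, X = 1) / 47,
    control = c(B = 0, H = 18, HV = 1, I = 1, J = 7, K = 0, N = 1, T = 1,
                U = 5, V = 5, W = 1, X = 2) / 42
  )
}

#' @rdname simulation_config
#' @export
default_region_rates <- function() {
  tibble::tribble(
    ~region, ~rate_patient, ~rate_control, ~rare_share_patient, ~rare_share_control,
    "complexI",    6.55, 5.40, 0.20, 0.26,
    "complexIII",  2.89, 2.29, 0.22, 0.24,
    "complexIV",   1.87, 1.76, 0.19, 0.34,
    "ATPsynthase", 1.70, 1.52, 0.25, 0.25,
    "rRNA",        4.00, 3.43, 0.18, 0.22,
    "tRNA",        0.70, 0.55, 0.10, 0.35,
    "noncoding",   8.30, 7.19, 0.30, 0.23
  )
}

.transitions <- c(A = "G", G = "A", C = "T", T = "C")
.transversions <- list(A = c("C", "T"), G = c("C", "T"),
                       C = c("A", "G"), T = c("A", "G"))

#' Simulate a case-control mtDNA cohort
#'
#' Draws, for each subject in turn and in documented order (haplogroup, then
#' marker variants, then per-region filler variants, then scores, then
#' heteroplasmy), a variant profile with the statistical structure the
#' downstream analysis assumes. Reproducible for a fixed seed from a single
#' pseudo-random stream; the global RNG state is left untouched.
#'
#' Every generated variant receives a consistent population frequency (first
#' draw wins for recurrent variants) and every non-synonymous variant a
#' pathogenicity score, so the generated frequency and score tables cover the
#' generated cohort completely. Planted per-region, per-group tallies are
#' recorded in `truth` for parameter-recovery checks.
#'
#' @param config An `mt_sim_config` from [simulation_config()].
#' @param model Gene model used to pick reference alleles and effect-steer
#'   coding variants (default: packaged model).
#' @param tree Marker tree supplying haplogroup-defining variants.
#' @return List of class `mt_sim`: `cohort` (an `mt_cohort`), `frequencies`,
#'   `scores` (tibbles usable directly in [annotate_cohort()]), `truth`
#'   (planted tallies), `config`.
#' @export
simulate_cohort <- function(config = simulation_config(),
                            model = mt_gene_model(),
                            tree = load_haplotree()) {
  stopifnot(inherits(config, "mt_sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed, kind = "Mersenne-Twister", sample.kind = "Rejection")

  labels <- names(config$haplogroup_freqs$patient)
  node_idx <- match(labels, tree$nodes$name)
  if (any(is.na(node_idx))) {
    stop("haplogroup label(s) absent from tree: ",
         paste(labels[is.na(node_idx)], collapse = ", "))
  }
  marker_sets <- setNames(tree$nodes$cumulative[node_idx], labels)

  # Haplogroup-defining sites are governed by the haplogroup draw alone:
  # keeping them out of the filler pools prevents random filler variants from
  # imitating another clade's markers and confounding the planted labels.
  marker_positions <- unique(c(
    11778L,
    unlist(lapply(tree$nodes$cumulative, function(k) {
      if (length(k) == 0) integer(0) else parse_variant_key(k)$position
    }))
  ))
  region_positions <- split(seq_len(model$genome_length), model$region_map)
  region_positions <- lapply(region_positions, setdiff, y = marker_positions)
  rr <- config$region_rates

  freq_env <- new.env(parent = emptyenv())   # key -> percent
  score_env <- new.env(parent = emptyenv())  # key -> score
  pf <- read_frequency_table(mt_frequency_file())
  for (i in seq_len(nrow(pf))) {
    key <- variant_key(pf$position[i], model$sequence[pf$position[i]], pf$alt[i])
    assign(key, pf$percent[i], envir = freq_env)
  }
  ps <- read_score_table(mt_score_file())
  for (i in seq_len(nrow(ps))) assign(ps$variant[i], ps$score[i], envir = score_env)

  subjects <- tibble::tibble(
    subject_id = c(sprintf("P%03d", seq_len(config$n_patients)),
                   sprintf("C%03d", seq_len(config$n_controls))),
    group = c(rep("patient", config$n_patients),
              rep("control", config$n_controls))
  )

  truth_keys <- expand.grid(region = .mt_regions,
                            group = c("patient", "control"),
                            stringsAsFactors = FALSE)
  truth <- tibble::as_tibble(truth_keys)
  truth$rare <- 0L
  truth$common <- 0L

  all_rows <- vector("list", nrow(subjects))
  true_hg <- character(nrow(subjects))
  for (si in seq_len(nrow(subjects))) {
    g <- subjects$group[si]
    sid <- subjects$subject_id[si]
    used <- integer(0)
    pos_v <- integer(0); ref_v <- character(0); alt_v <- character(0)
    het_v <- numeric(0)

    add_variant <- function(pos, alt, het = 100) {
      pos_v[[length(pos_v) + 1L]] <<- pos
      ref_v[[length(ref_v) + 1L]] <<- model$sequence[pos]
      alt_v[[length(alt_v) + 1L]] <<- alt
      het_v[[length(het_v) + 1L]] <<- het
      used <<- c(used, pos)
    }

    # 1. haplogroup
    hg <- sample(labels, 1, prob = config$haplogroup_freqs[[g]])
    true_hg[si] <- hg
    # 2. marker variants
    markers <- marker_sets[[hg]]
    if (length(markers) > 0 && runif(1) > config$marker_fidelity) {
      markers <- markers[-sample(length(markers), 1)]
    }
    if (length(markers) > 0) {
      mk <- parse_variant_key(markers)
      for (j in seq_len(nrow(mk))) add_variant(mk$position[j], mk$alt[j])
    }
    # primary mutation
    if (config$force_primary && g == "patient") {
      het <- if (runif(1) < config$het_prob) {
        runif(1, config$het_range[1], config$het_range[2])
      } else 100
      add_variant(11778L, "A", het)
    }
    # 3. per-region filler variants
    for (ri in seq_len(nrow(rr))) {
      region <- rr$region[ri]
      rate <- if (g == "patient") rr$rate_patient[ri] else rr$rate_control[ri]
      rare_share <- if (g == "patient") rr$rare_share_patient[ri] else rr$rare_share_control[ri]
      n_draw <- rpois(1, rate)
      if (n_draw == 0) next
      pool <- region_positions[[region]]
      coding <- region %in% .coding_regions
      for (k in seq_len(n_draw)) {
        # class and effect targets are decided first; candidate variants are
        # redrawn when an already-assigned population frequency contradicts
        # the wanted rarity class (a population frequency is one number per
        # variant, so class steering has to happen through variant choice)
        want_ns <- coding && runif(1) < config$ns_prob
        want_rare <- runif(1) < rare_share
        drawn <- NULL
        for (try in 1:20) {
          pos <- sample(pool, 1)
          if (pos %in% used) next
          ref <- model$sequence[pos]
          alt <- if (runif(1) < config$ts_prob) {
            unname(.transitions[ref])
          } else {
            sample(.transversions[[ref]], 1)
          }
          key <- variant_key(pos, ref, alt)
          cls_ok <- if (exists(key, envir = freq_env)) {
            (get(key, envir = freq_env) <= 0.5) == want_rare
          } else TRUE
          eff_ok <- if (coding) {
            cat_ <- .category_of(pos, alt, model)
            (want_ns && cat_ == "non-synonymous") ||
              (!want_ns && cat_ == "synonymous")
          } else TRUE
          if ((cls_ok && eff_ok) || try == 20) {
            drawn <- list(pos = pos, alt = alt, key = key)
            break
          }
        }
        if (is.null(drawn)) next
        add_variant(drawn$pos, drawn$alt)
        if (!exists(drawn$key, envir = freq_env)) {
          pct <- if (want_rare) runif(1, 0.01, 0.5) else runif(1, 0.6, 30)
          assign(drawn$key, round(pct, 3), envir = freq_env)
        }
        pct <- get(drawn$key, envir = freq_env)
        cls <- if (pct <= 0.5) "rare" else "common"
        tr <- truth$region == region & truth$group == g
        truth[[cls]][tr] <- truth[[cls]][tr] + 1L
      }
    }
    # 4. scores for non-synonymous variants
    if (length(pos_v) > 0) {
      for (j in seq_along(pos_v)) {
        if (.category_of(pos_v[j], alt_v[j], model) != "non-synonymous") next
        key <- variant_key(pos_v[j], ref_v[j], alt_v[j])
        if (!exists(key, envir = score_env)) {
          assign(key, round(rbeta(1, config$score_shape[1], config$score_shape[2]), 4),
                 envir = score_env)
        }
      }
    }
    all_rows[[si]] <- tibble::tibble(
      subject_id = sid, position = pos_v, ref = ref_v, alt = alt_v,
      heteroplasmy = het_v
    )
  }

  variants <- dplyr::bind_rows(all_rows)
  subjects$true_haplogroup <- true_hg

  fkeys <- ls(freq_env)
  frequencies <- dplyr::bind_cols(
    parse_variant_key(fkeys),
    tibble::tibble(percent = vapply(fkeys, get, numeric(1), envir = freq_env))
  )
  skeys <- ls(score_env)
  scores <- tibble::tibble(
    variant = skeys,
    score = vapply(skeys, get, numeric(1), envir = score_env)
  )

  cohort <- mt_cohort(subjects, variants)
  structure(list(cohort = cohort, frequencies = frequencies, scores = scores,
                 truth = truth, config = config),
            class = "mt_sim")
}

#' @export
print.mt_sim <- function(x, ...) {
  cat("synthetic cohort simulation (seed", x$config$seed, "):\n")
  print(x$cohort)
  invisible(x)
}
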