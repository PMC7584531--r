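# Shared fixtures: cached packaged model/tree and small in-code cohorts.

.helper_cache <- new.env(parent = emptyenv())

test_model <- function() {
  if (is.null(.helper_cache$model)) .helper_cache$model <- mt_gene_model()
  .helper_cache$model
}

test_tree <- function() {
  if (is.null(.helper_cache$tree)) .helper_cache$tree <- load_haplotree()
  .helper_cache$tree
}

# A tiny hand-built cohort over the packaged reference. Variants are given as
# a data.frame of (subject_id, position, alt [, heteroplasmy]); ref alleles
# are taken from the model sequence.
make_cohort <- function(variants, subjects = NULL) {
  model <- test_model()
  if (!"heteroplasmy" %in% names(variants)) variants$heteroplasmy <- 100
  variants$ref <- model$sequence[variants$position]
  if (is.null(subjects)) {
    ids <- unique(variants$subject_id)
    subjects <- data.frame(
      subject_id = ids,
      group = ifelse(grepl("^P", ids), "patient", "control")
    )
  }
  mt_cohort(subjects, variants[, c("subject_id", "position", "ref", "alt",
                                   "heteroplasmy")])
}

# Frequency table rows in m.-notation against the packaged reference.
make_freq <- function(positions, alts, percents) {
  tibble::tibble(position = as.integer(positions), alt = alts,
                 percent = percents)
}

# Null-cohort configuration: identical generating processes in both groups
# and no planted primary mutation.
null_config <- function(seed, n = 47L, m = 42L) {
  p <- default_haplogroup_freqs()$patient
  rr <- default_region_rates()
  rr$rate_control <- rr$rate_patient
  rr$rare_share_control <- rr$rare_share_patient
  simulation_config(
    n_patients = n, n_controls = m,
    haplogroup_freqs = list(patient = p, control = p),
    region_rates = rr, force_primary = FALSE, seed = seed
  )
}

# Independent brute-force two-sided Fisher p from first principles: enumerate
# all tables with the observed margins using choose() directly.
enumerate_fisher_p <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; m <- a + c; N <- n1 + n2
  xs <- max(0, m - n2):min(m, n1)
  probs <- vapply(xs, function(x) {
    exp(lchoose(n1, x) + lchoose(n2, m - x) - lchoose(N, m))
  }, numeric(1))
  p0 <- probs[xs == a]
  sum(probs[probs <= p0 * (1 + 1e-7)])
}
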