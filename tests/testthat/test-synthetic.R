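test_that("simulation is reproducible and leaves the global RNG untouched", {
  set.seed(999)
  before <- .Random.seed
  s1 <- simulate_cohort(simulation_config(seed = 5))
  expect_identical(.Random.seed, before)
  s2 <- simulate_cohort(simulation_config(seed = 5))
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$frequencies, s2$frequencies)
  expect_identical(s1$scores, s2$scores)
  s3 <- simulate_cohort(simulation_config(seed = 6))
  expect_false(identical(s1$cohort$variants, s3$cohort$variants))
})

test_that("every patient carries the primary mutation; controls never do", {
  sim <- simulate_cohort(simulation_config(seed = 13))
  v <- sim$cohort$variants
  carriers <- unique(v$subject_id[v$position == 11778 & v$alt == "A"])
  s <- sim$cohort$subjects
  expect_setequal(carriers, s$subject_id[s$group == "patient"])
  # heteroplasmy: mostly homoplasmic with occasional 70-95% levels
  h <- v$heteroplasmy[v$position == 11778]
  expect_true(all(h == 100 | (h >= 70 & h <= 95)))
})

test_that("all-zero regional rates leave only planted structure", {
  rr <- default_region_rates()
  rr[, c("rate_patient", "rate_control")] <- 0
  # marker-free configuration: everyone drawn as H (rCRS baseline)
  freqs <- list(patient = c(H = 1), control = c(H = 1))
  cfg <- simulation_config(n_patients = 5, n_controls = 4,
                           haplogroup_freqs = freqs, region_rates = rr,
                           seed = 2)
  sim <- simulate_cohort(cfg)
  v <- sim$cohort$variants
  expect_equal(sort(unique(v$subject_id)),
               sort(sim$cohort$subjects$subject_id[
                 sim$cohort$subjects$group == "patient"]))
  expect_true(all(v$position == 11778))
  counts <- table(v$subject_id)
  expect_true(all(counts == 1))  # exactly one variant per patient
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(haplogroup_freqs = list(
    patient = c(H = 0.7, K = 0.2), control = c(H = 1)
  )), "summing to 1")
  rr <- default_region_rates()
  rr$rate_patient[1] <- -1
  expect_error(simulation_config(region_rates = rr), ">= 0")
  rr2 <- default_region_rates()
  rr2$rare_share_patient[1] <- 1.5
  expect_error(simulation_config(region_rates = rr2), "rare shares")
  expect_error(simulation_config(marker_fidelity = 2), "marker_fidelity")
})

test_that("marker fidelity below one drops exactly one marker per subject", {
  tree <- test_tree()
  marker_sets <- setNames(tree$nodes$cumulative, tree$nodes$name)
  count_markers <- function(sim) {
    v <- sim$cohort$variants
    keys_by_subject <- split(variant_key(v$position, v$ref, v$alt),
                             v$subject_id)
    s <- sim$cohort$subjects
    vapply(seq_len(nrow(s)), function(i) {
      expected <- marker_sets[[s$true_haplogroup[i]]]
      sum(expected %in% keys_by_subject[[s$subject_id[i]]])
    }, numeric(1))
  }
  full <- simulate_cohort(simulation_config(seed = 3, marker_fidelity = 1))
  expected_full <- vapply(full$cohort$subjects$true_haplogroup,
                          function(h) length(marker_sets[[h]]), numeric(1))
  expect_equal(count_markers(full), unname(expected_full))
  low <- simulate_cohort(simulation_config(seed = 3, marker_fidelity = 0))
  expected_low <- vapply(low$cohort$subjects$true_haplogroup,
                         function(h) max(0, length(marker_sets[[h]]) - 1),
                         numeric(1))
  expect_equal(count_markers(low), unname(expected_low))
})

test_that("simulated rare shares recover the configured rates at scale", {
  cfg <- simulation_config(n_patients = 500, n_controls = 500, seed = 41)
  sim <- simulate_cohort(cfg)
  co <- annotate_cohort(sim$cohort, test_model(), sim$frequencies, sim$scores)
  tree <- test_tree()
  marker_keys <- unique(unlist(tree$nodes$cumulative))
  v <- co$variants
  v <- dplyr::left_join(v, co$subjects[, c("subject_id", "group")],
                        by = "subject_id")
  v$key <- variant_key(v$position, v$ref, v$alt)
  filler <- v[!v$key %in% c(marker_keys, "m.11778G>A"), ]
  # each filler occurrence's rarity class is an independent Bernoulli draw
  # at the configured per-region share
  rr <- cfg$region_rates
  checked <- 0
  for (g in c("patient", "control")) {
    share_col <- if (g == "patient") "rare_share_patient" else "rare_share_control"
    for (r in rr$region) {
      fu <- filler[filler$group == g & filler$region == r, ]
      n <- nrow(fu)
      if (n < 50) next
      p <- rr[[share_col]][rr$region == r]
      se <- sqrt(p * (1 - p) / n)
      expect_lt(abs(mean(fu$rarity == "rare") - p), 3 * se,
                label = sprintf("rare share %s/%s", g, r))
      checked <- checked + 1
    }
  }
  expect_gte(checked, 8)
})

test_that("study fixture tables reproduce every published odds ratio", {
  fx <- lhon_fixture()
  expect_gte(length(fx$tables), 19)
  expect_equal(unname(fx$tables[["haplogroup:K"]]$counts), c(5, 42, 0, 42))
  expect_equal(unname(fx$tables[["snv:m.73A>G"]]$counts), c(31, 16, 18, 24))
  for (nm in names(fx$tables)) {
    tb <- fx$tables[[nm]]
    res <- association_2x2(tb$counts[["a"]], tb$counts[["b"]],
                           tb$counts[["c"]], tb$counts[["d"]])
    expect_equal(round(res$odds_ratio, 3), tb$published$or, label = nm)
    expect_equal(res$haldane_applied, tb$published$haldane, label = nm)
  }
  # group margins are consistent throughout
  for (tb in fx$tables) {
    expect_equal(tb$counts[["a"]] + tb$counts[["b"]], 47)
    expect_equal(tb$counts[["c"]] + tb$counts[["d"]], 42)
  }
})

test_that("fixture regional tables reproduce published statistics from raw counts", {
  fx <- lhon_fixture()
  for (i in seq_len(nrow(fx$tstv))) {
    row <- fx$tstv[i, ]
    if (is.na(row$or)) next
    res <- association_2x2(row$ts_pat, row$tv_pat, row$ts_con, row$tv_con)
    expect_equal(round(res$odds_ratio, 3), row$or, label = row$region)
    expect_equal(round(res$p_value, 3), row$p, tolerance = 2e-3,
                 label = paste("p", row$region))
  }
  for (i in seq_len(nrow(fx$nss))) {
    row <- fx$nss[i, ]
    res <- association_2x2(row$ns_pat, row$s_pat, row$ns_con, row$s_con)
    expect_equal(round(res$odds_ratio, 3), row$or, label = row$region)
    expect_equal(round(res$ci_low, 3), row$ci_low, label = row$region)
    expect_equal(round(res$ci_high, 3), row$ci_high, label = row$region)
  }
})
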