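load_fixture <- function() {
  v <- data.frame(
    subject_id = c("P1", "P1", "P1", "C1", "C1"),
    position = c(9055L, 3497L, 11778L, 8836L, 14831L),
    alt = c("A", "T", "A", "G", "A")
  )
  scores <- tibble::tibble(
    variant = c("m.9055G>A", "m.3497C>T", "m.11778G>A", "m.8836A>G",
                "m.14831G>A"),
    score = c(0.3, 0.7, 0.85, 0.52, 0.47)
  )
  annotate_cohort(make_cohort(v), test_model(), scores = scores)
}

test_that("loads sum non-synonymous scores with threshold and exclusion rules", {
  co <- load_fixture()
  loads <- compute_loads(co)
  p1 <- loads[loads$subject_id == "P1", ]
  # scores {0.3, 0.7}; m.11778G>A excluded despite its 0.85 score
  expect_equal(p1$total_load, 1.0)
  expect_equal(p1$threshold_load, 0.7)
  expect_equal(p1$n_ns, 2L)
  c1 <- loads[loads$subject_id == "C1", ]
  expect_equal(c1$total_load, 0.52 + 0.47)
  expect_equal(c1$threshold_load, 0.52)
  # a profile whose only NS variant is the primary mutation loads to zero
  only_primary <- annotate_cohort(
    make_cohort(data.frame(subject_id = "P9", position = 11778L, alt = "A")),
    test_model(), scores = tibble::tibble(variant = "m.11778G>A", score = 0.85)
  )
  expect_equal(compute_loads(only_primary)$total_load, 0)
})

test_that("loads are additive over disjoint variant subsets", {
  co <- load_fixture()
  whole <- compute_loads(co)
  v <- co$variants
  part1 <- co; part1$variants <- v[v$position < 10000, ]
  part2 <- co; part2$variants <- v[v$position >= 10000, ]
  attr(part1, "annotated") <- TRUE
  attr(part2, "annotated") <- TRUE
  split_sum <- compute_loads(part1)$total_load + compute_loads(part2)$total_load
  expect_equal(split_sum, whole$total_load)
})

test_that("raising the threshold never increases the threshold load", {
  co <- load_fixture()
  thresholds <- c(0.2, 0.4, 0.6, 0.8)
  tl <- vapply(thresholds,
               function(t) sum(compute_loads(co, threshold = t)$threshold_load),
               numeric(1))
  expect_true(all(diff(tl) <= 0))
  expect_true(all(compute_loads(co)$threshold_load <=
                    compute_loads(co)$total_load))
})

test_that("missing scores skip with a warning by default, or fail on request", {
  v <- data.frame(subject_id = "P1", position = c(9055L, 8836L), alt = c("A", "G"))
  co <- annotate_cohort(make_cohort(v), test_model(),
                        scores = tibble::tibble(variant = "m.9055G>A",
                                                score = 0.3))
  expect_warning(loads <- compute_loads(co), "m.8836A>G.*skipped")
  expect_equal(loads$total_load, 0.3)
  expect_equal(loads$n_unscored, 1L)
  expect_error(compute_loads(co, missing_score = "fail"), "m.8836A>G")
})

test_that("scores accept amino-acid-change keys as an alternative", {
  v <- data.frame(subject_id = "P1", position = 9055L, alt = "A")
  co <- annotate_cohort(make_cohort(v), test_model(),
                        scores = tibble::tibble(protein_change = "p.Ala177Thr",
                                                score = 0.41))
  expect_equal(compute_loads(co)$total_load, 0.41)
})

test_that("group comparison reports t-tests and the high-score carrier table", {
  sim <- simulate_cohort(simulation_config(seed = 29))
  co <- annotate_cohort(sim$cohort, test_model(), sim$frequencies, sim$scores)
  cl <- compare_loads(co)
  expect_setequal(cl$summary$group, c("patient", "control"))
  direct <- pooled_t_test(
    cl$summary$mean_total[cl$summary$group == "patient"],
    cl$summary$sd_total[cl$summary$group == "patient"], n_patients(co),
    cl$summary$mean_total[cl$summary$group == "control"],
    cl$summary$sd_total[cl$summary$group == "control"], n_controls(co)
  )
  expect_equal(cl$t_total$p_value, direct$p_value)
  ct <- carrier_table(co, score_gt = 0.5)
  expect_equal(cl$carriers$a, ct$a)
  expect_equal(cl$carriers$d, ct$d)
  # two identical groups give t = 0
  ids <- co$subjects$subject_id
  mirror <- co
  mirror$subjects <- tibble::tibble(
    subject_id = c(paste0("A", ids), paste0("B", ids)),
    group = rep(c("patient", "control"), each = length(ids))
  )
  mv <- co$variants
  mirror$variants <- dplyr::bind_rows(
    dplyr::mutate(mv, subject_id = paste0("A", .data$subject_id)),
    dplyr::mutate(mv, subject_id = paste0("B", .data$subject_id))
  )
  attr(mirror, "annotated") <- TRUE
  cl_m <- compare_loads(mirror)
  expect_equal(cl_m$t_total$t_statistic, 0)
  expect_equal(cl_m$t_total$p_value, 1)
})

test_that("monte-carlo score draws recover the configured distribution mean", {
  cfg <- simulation_config(n_patients = 200, n_controls = 200, seed = 37)
  sim <- simulate_cohort(cfg)
  co <- annotate_cohort(sim$cohort, test_model(), sim$frequencies, sim$scores)
  v <- co$variants
  tree <- test_tree()
  marker_keys <- unique(unlist(tree$nodes$cumulative))
  v$key <- variant_key(v$position, v$ref, v$alt)
  filler_ns <- v[v$category == "non-synonymous" &
                   !v$key %in% c(marker_keys, "m.11778G>A"), ]
  scores <- unique(filler_ns[, c("key", "score")])$score
  mu <- cfg$score_shape[1] / sum(cfg$score_shape)
  sigma <- sqrt(prod(cfg$score_shape) /
                  (sum(cfg$score_shape)^2 * (sum(cfg$score_shape) + 1)))
  se <- sigma / sqrt(length(scores))
  expect_gt(length(scores), 100)
  expect_lt(abs(mean(scores) - mu), 2 * se)
})
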