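# Small annotated cohort used across burden tests: 3 subjects sharing one
# transition in rRNA, plus assorted region/rarity/effect structure.
burden_fixture <- function() {
  model <- test_model()
  tv_alt <- function(pos) {  # transversion alt for the packaged ref base
    setdiff(c("A", "C", "G", "T"),
            c(model$sequence[pos],
              c(A = "G", G = "A", C = "T", T = "C")[[model$sequence[pos]]]))[1]
  }
  v <- tibble::tribble(
    ~subject_id, ~position, ~alt,
    "P1", 709L,  "A",          # rRNA transition (shared by all three)
    "P2", 709L,  "A",
    "C1", 709L,  "A",
    "P1", 11778L, "A",         # primary mutation, excluded from tallies
    "P2", 11778L, "A",
    "P1", 9055L, "A",          # ATPsynthase, non-synonymous, common
    "P1", 3480L, "G",          # complexI, synonymous, common
    "C1", 3497L, "T",          # complexI, non-synonymous, rare
    "C1", 73L,   "G",          # noncoding transition, common
    "P2", 73L,   "G",
    "C1", 800L,  "X"           # rRNA transversion (alt filled in below)
  )
  v$alt[v$position == 800L] <- tv_alt(800L)
  tv <- tibble::tibble(subject_id = "C1", position = 6000L,
                       alt = tv_alt(6000L))  # complexIV transversion, unscored freq
  v <- dplyr::bind_rows(v, tv)
  co <- make_cohort(as.data.frame(v))
  freq <- make_freq(
    c(709L, 11778L, 9055L, 3480L, 3497L, 73L),
    c("A", "A", "A", "G", "T", "G"),
    c(12, 0.26, 2.1, 2.3, 0.35, 76)
  )
  scores <- tibble::tibble(variant = c("m.9055G>A", "m.3497C>T", "m.11778G>A"),
                           score = c(0.41, 0.63, 0.85))
  annotate_cohort(co, model, freq, scores)
}

test_that("occurrence and unique modes count shared variants as documented", {
  co <- burden_fixture()
  occ <- tally_burden(co, "rRNA", "occurrence")
  uni <- tally_burden(co, "rRNA", "unique")
  expect_equal(occ$ts[occ$group == "patient"], 2L)
  expect_equal(occ$ts[occ$group == "control"], 1L)
  expect_equal(uni$ts[uni$group == "patient"], 1L)
  expect_equal(uni$ts[uni$group == "control"], 1L)
  # unique counts never exceed occurrence counts
  for (r in c("complexI", "complexIV", "noncoding", "overall")) {
    o <- tally_burden(co, r, "occurrence")
    u <- tally_burden(co, r, "unique")
    for (col in c("ts", "tv", "rare", "common", "ns", "s")) {
      expect_true(all(u[[col]] <= o[[col]]), label = paste(r, col))
    }
  }
})

test_that("empty cohorts give all-zero burdens", {
  co <- burden_fixture()
  empty <- mt_cohort(co$subjects,
                     co$variants[0, c("subject_id", "position", "ref", "alt",
                                      "heteroplasmy")])
  empty <- annotate_cohort(empty, test_model())
  b <- tally_burden(empty, "overall")
  expect_true(all(b[, c("ts", "tv", "rare", "common", "ns", "s")] == 0))
})

test_that("the primary-mutation exclusion applies to complex I and overall only", {
  co <- burden_fixture()
  # with the default exclusion: m.11778G>A absent everywhere it could count
  ci <- tally_burden(co, "complexI")
  expect_equal(ci$ts[ci$group == "patient"], 1L)   # only m.3480A>G
  expect_equal(ci$ns[ci$group == "patient"], 0L)
  # without exclusions the two patient copies reappear
  ci_all <- tally_burden(co, "complexI", exclusions = character(0))
  expect_equal(ci_all$ts[ci_all$group == "patient"], 3L)
  expect_equal(ci_all$ns[ci_all$group == "patient"], 2L)
  # occurrence-mode overall drops one copy per carrying patient,
  # unique-mode overall exactly one
  ov <- tally_burden(co, "overall")
  ov_all <- tally_burden(co, "overall", exclusions = character(0))
  expect_equal(ov_all$ts[ov_all$group == "patient"] -
                 ov$ts[ov$group == "patient"], 2L)
  ou <- tally_burden(co, "overall_unique")
  ou_all <- tally_burden(co, "overall_unique", exclusions = character(0))
  expect_equal(ou_all$ts[ou_all$group == "patient"] -
                 ou$ts[ou$group == "patient"], 1L)
})

test_that("per-region tallies sum to the overall tally under identical exclusions", {
  sim <- simulate_cohort(simulation_config(seed = 17))
  co <- annotate_cohort(sim$cohort, test_model(), sim$frequencies, sim$scores)
  regions <- c("complexI", "complexIII", "complexIV", "ATPsynthase",
               "rRNA", "tRNA", "noncoding")
  per_region <- lapply(regions, function(r) tally_burden(co, r, "occurrence"))
  total <- dplyr::bind_rows(per_region)
  ov <- tally_burden(co, "overall", "occurrence")
  for (g in c("patient", "control")) {
    for (col in c("ts", "tv", "rare", "common", "ns", "s")) {
      expect_equal(sum(total[[col]][total$group == g]),
                   ov[[col]][ov$group == g],
                   label = paste("overall", g, col))
    }
  }
})

test_that("ts/tv ratios match documented arithmetic including the n/a case", {
  expect_equal(round(ts_tv_ratio(1189, 34), 2), 34.97)
  expect_equal(round(ts_tv_ratio(298, 10), 2), 29.80)
  expect_true(is.na(ts_tv_ratio(188, 0)))
})

test_that("compare_burden equals a direct call to the exact statistics", {
  co <- burden_fixture()
  b <- tally_burden(co, "rRNA", "occurrence")
  cmp <- compare_burden(b, "ts_vs_tv")
  pat <- b[b$group == "patient", ]
  con <- b[b$group == "control", ]
  direct <- association_2x2(pat$ts, pat$tv, con$ts, con$tv)
  expect_equal(cmp$p_value, direct$p_value)
  expect_equal(cmp$odds_ratio, direct$odds_ratio)
  expect_equal(cmp$ci_low, direct$ci_low)
  expect_equal(cmp$haldane_applied, direct$haldane_applied)
  # identical burdens give OR 1, p 1
  b_id <- b
  b_id$ts <- c(5L, 5L); b_id$tv <- c(2L, 2L)
  cmp_id <- compare_burden(b_id, "ts_vs_tv")
  expect_equal(cmp_id$odds_ratio, 1)
  expect_equal(cmp_id$p_value, 1)
  # degenerate contrast (no transversions anywhere) is n/a
  b_na <- b
  b_na$tv <- c(0L, 0L)
  expect_true(is.na(compare_burden(b_na, "ts_vs_tv")$p_value))
  # mode mismatch is an error
  b_mix <- dplyr::bind_rows(tally_burden(co, "rRNA", "occurrence")[1, ],
                            tally_burden(co, "rRNA", "unique")[2, ])
  expect_error(compare_burden(b_mix, "ts_vs_tv"), "share region and mode")
})

test_that("carrier tables implement at-least-one-qualifying-variant logic", {
  co <- burden_fixture()
  # rare complex I carrier: only C1 (m.3497C>T)
  ct <- carrier_table(co, region = "complexI", rarity = "rare")
  expect_equal(ct$a, 0L); expect_equal(ct$b, 2L)
  expect_equal(ct$c, 1L); expect_equal(ct$d, 0L)
  # high-score carrier excludes the primary mutation: P1 via 9055 (0.41)?
  # threshold 0.5 leaves only C1 via m.3497C>T (0.63)
  ct2 <- carrier_table(co, score_gt = 0.5)
  expect_equal(ct2$a, 0L)
  expect_equal(ct2$c, 1L)
  # lowering the threshold brings in P1's m.9055G>A
  ct3 <- carrier_table(co, score_gt = 0.4)
  expect_equal(ct3$a, 1L)
  # predicate matching nothing: zero carriers, full non-carrier margins
  ct4 <- carrier_table(co, region = "complexIII", rarity = "rare")
  expect_equal(unlist(ct4[c("a", "b", "c", "d")], use.names = FALSE),
               c(0L, 2L, 0L, 1L))
  # score filter without scores attached is an error
  co_ns <- annotate_cohort(make_cohort(
    data.frame(subject_id = c("P1", "C1"), position = c(73L, 73L), alt = "G")
  ), test_model())
  expect_error(carrier_table(co_ns, score_gt = 0.5), "no scores")
})

test_that("rarity spectrum excludes unknowns and flags empty regions", {
  co <- burden_fixture()
  sp <- rarity_spectrum(co)
  r <- sp[sp$region == "complexIV" & sp$group == "control", ]
  # the only complex IV variant has no frequency entry: unknown, NA shares
  expect_equal(r$unknown_rarity, 1L)
  expect_true(is.na(r$share_rare))
  # complex I patients: one common variant (m.3480A>G) after exclusion
  ci <- sp[sp$region == "complexI" & sp$group == "patient", ]
  expect_equal(ci$share_common, 1)
  # all-rare toy cohort: share 1 in every populated region
  toy <- make_cohort(data.frame(subject_id = c("P1", "C1"),
                                position = c(3497L, 3497L), alt = "T"))
  toy <- annotate_cohort(toy, test_model(),
                         make_freq(3497L, "T", 0.35))
  sp_toy <- rarity_spectrum(toy)
  pop <- sp_toy[sp_toy$rare + sp_toy$common > 0, ]
  expect_true(all(pop$share_rare == 1))
})

test_that("planted simulator tallies are recovered exactly from the pipeline", {
  sim <- simulate_cohort(simulation_config(seed = 23))
  co <- annotate_cohort(sim$cohort, test_model(), sim$frequencies, sim$scores)
  tree <- test_tree()
  marker_keys <- unique(unlist(tree$nodes$cumulative))
  v <- dplyr::left_join(co$variants,
                        co$subjects[, c("subject_id", "group")],
                        by = "subject_id")
  v$key <- variant_key(v$position, v$ref, v$alt)
  filler <- v[!v$key %in% c(marker_keys, "m.11778G>A"), ]
  # generator bookkeeping is the oracle: realized rare/common occurrence
  # counts per region and group must match the planted tallies exactly
  for (g in c("patient", "control")) {
    for (r in unique(sim$truth$region)) {
      fr <- filler[filler$group == g & filler$region == r, ]
      tr <- sim$truth[sim$truth$group == g & sim$truth$region == r, ]
      expect_equal(sum(fr$rarity == "rare"), tr$rare,
                   label = paste("rare", g, r))
      expect_equal(sum(fr$rarity == "common"), tr$common,
                   label = paste("common", g, r))
    }
  }
})
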