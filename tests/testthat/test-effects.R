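test_that("transition/transversion classification is correct and symmetric", {
  pairs <- expand.grid(ref = c("A", "C", "G", "T"), alt = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  cls <- classify_substitution(pairs$ref, pairs$alt)
  rev_cls <- classify_substitution(pairs$alt, pairs$ref)
  expect_equal(cls, rev_cls)  # symmetry over all 12 ordered pairs
  purine <- c("A", "G")
  expect_equal(cls == "transition",
               (pairs$ref %in% purine) == (pairs$alt %in% purine))
  expect_equal(classify_substitution("G", "A"), "transition")
  expect_equal(classify_substitution("C", "A"), "transversion")
  expect_equal(classify_substitution("T", "C"), "transition")
  expect_error(classify_substitution("A", "A"), "differ")
  expect_error(classify_substitution("A", "N"), "single bases")
})

test_that("effect annotation reproduces the documented protein changes", {
  model <- test_model()
  cases <- tibble::tribble(
    ~position, ~ref, ~alt, ~category,        ~protein_change, ~locus,
    9055L,  "G", "A", "non-synonymous", "p.Ala177Thr", "MT-ATP6",
    3480L,  "A", "G", "synonymous",     "p.Lys58=",    "MT-ND1",
    11299L, "T", "C", "synonymous",     "p.Thr180=",   "MT-ND4",
    14167L, "C", "T", "synonymous",     "p.Glu169=",   "MT-ND6",
    3497L,  "C", "T", "non-synonymous", "p.Ala64Val",  "MT-ND1",
    8836L,  "A", "G", "non-synonymous", "p.Met104Val", "MT-ATP6",
    14831L, "G", "A", "non-synonymous", "p.Ala29Thr",  "MT-CYB",
    11778L, "G", "A", "non-synonymous", "p.Arg340His", "MT-ND4"
  )
  eff <- annotate_effects(cases$position, cases$ref, cases$alt, model)
  expect_equal(eff$category, cases$category)
  expect_equal(eff$protein_change, cases$protein_change)
  expect_equal(eff$locus, cases$locus)
})

test_that("non-protein loci get rna-change / non-coding-change categories", {
  model <- test_model()
  # control region, rRNA, tRNA representatives (refs from the model sequence)
  pos <- c(73L, 709L, 12308L)
  ref <- model$sequence[pos]
  alt <- unname(c(A = "G", G = "A", C = "T", T = "C")[ref])
  eff <- annotate_effects(pos, ref, alt, model)
  expect_equal(eff$category, c("non-coding-change", "rna-change", "rna-change"))
  expect_true(all(eff$protein_change == ""))
})

test_that("reference mismatch is an error naming position and expected base", {
  model <- test_model()
  wrong <- setdiff(c("A", "C", "G", "T"), model$sequence[5000])[1]
  expect_error(annotate_effect(5000, wrong, "T", model),
               "position 5000.*model has")
})

test_that("effect calls agree with direct codon translation (independent oracle)",
{
  model <- test_model()
  mito_code <- Biostrings::getGeneticCode("2")  # vertebrate mitochondrial
  coding <- model$features[model$features$product_class %in%
                             c("complexI", "complexIII", "complexIV",
                               "ATPsynthase"), ]
  set.seed(81)
  aa1to3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
              Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
              L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
              S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
              `*` = "Ter")
  for (rep in 1:200) {
    gi <- sample(nrow(coding), 1)
    feat <- coding[gi, ]
    len <- feat$end - feat$start + 1
    n_codon <- len %/% 3
    ci <- sample(n_codon, 1)
    cp <- sample(3, 1)
    # heavy-strand coordinate of the sampled codon position
    pos <- if (feat$strand == "heavy") {
      feat$start + (ci - 1L) * 3L + (cp - 1L)
    } else {
      feat$end - (ci - 1L) * 3L - (cp - 1L)
    }
    # skip overlap positions where the primary locus differs
    if (model$locus_map[pos] != feat$locus) next
    ref <- model$sequence[pos]
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    eff <- annotate_effects(pos, ref, alt, model)
    # oracle: translate both codons directly from the sense sequence
    sense <- if (feat$strand == "heavy") {
      model$sequence[feat$start:feat$end]
    } else {
      as.character(rev(setNames(c("T", "G", "C", "A"),
                                c("A", "C", "G", "T"))[
                                  model$sequence[feat$start:feat$end]]))
    }
    codon <- sense[(3 * ci - 2):(3 * ci)]
    alt_codon <- codon
    alt_codon[cp] <- if (feat$strand == "heavy") alt else {
      c(A = "T", C = "G", G = "C", T = "A")[[alt]]
    }
    tr <- function(cd) {
      as.character(Biostrings::translate(
        Biostrings::DNAString(paste(cd, collapse = "")),
        genetic.code = mito_code, no.init.codon = TRUE
      ))
    }
    ref_aa <- tr(codon)
    alt_aa <- tr(alt_codon)
    expected_cat <- if (ref_aa == alt_aa) "synonymous" else "non-synonymous"
    expect_equal(eff$category, expected_cat,
                 label = sprintf("category at m.%d%s>%s", pos, ref, alt))
    expect_equal(eff$codon_index, ci)
    if (expected_cat == "non-synonymous") {
      expect_equal(eff$protein_change,
                   sprintf("p.%s%d%s", aa1to3[[ref_aa]], ci, aa1to3[[alt_aa]]))
    } else {
      expect_equal(eff$protein_change, sprintf("p.%s%d=", aa1to3[[ref_aa]], ci))
    }
  }
})

test_that("third-position wobble changes preserving the amino acid are synonymous", {
  model <- test_model()
  # four-fold degenerate families under the vertebrate mito code
  fourfold <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")
  feat <- model$features[model$features$locus == "MT-CO1", ]
  len <- feat$end - feat$start + 1
  found <- 0
  for (ci in seq_len(len %/% 3)) {
    start <- feat$start + (ci - 1) * 3
    codon <- model$sequence[start:(start + 2)]
    if (!paste(codon[1:2], collapse = "") %in% fourfold) next
    pos <- start + 2L
    if (model$locus_map[pos] != "MT-CO1") next
    ref <- model$sequence[pos]
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      eff <- annotate_effects(pos, ref, alt, model)
      expect_equal(eff$category, "synonymous")
    }
    found <- found + 1
    if (found >= 10) break
  }
  expect_gte(found, 5)
})

test_that("overlap positions report effects for both reading frames", {
  model <- test_model()
  # inside the ATP8/ATP6 overlap (8527-8572)
  pos <- 8540L
  ref <- model$sequence[pos]
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  eff <- annotate_effects(pos, ref, alt, model)
  expect_equal(eff$locus, "MT-ATP8")
  expect_match(eff$overlap_effects, "MT-ATP6:p\\.")
})
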