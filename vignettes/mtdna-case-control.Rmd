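---
title: "Methods: whole-mtDNA case-control variation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-mtDNA case-control variation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`mtassoc` analyses mitochondrial genome variation between a patient and a
control group. The underlying model is deliberately simple and mirrors how
this literature analyses whole-mtDNA resequencing data: each subject
contributes a set of homoplasmic-or-near-homoplasmic single-nucleotide
substitutions relative to the rCRS reference; every substitution is
annotated (locus, functional region, transition/transversion, coding effect,
population rarity, pathogenicity score); and group comparisons are exact
2×2 tests on counts — of carriers, of haplogroup membership, or of regional
tallies — plus t-tests on per-subject score sums. No regression, haplotype
or permutation machinery is involved: the statistical unit is either the
subject (carrier and haplogroup analyses, variant loads) or the variant
observation (regional burden tallies).

The motivating design is a male LHON cohort in which every patient carries
the primary complex-I mutation m.11778G>A (MT-ND4, p.Arg340His). Because
that mutation defines the patient group, it is excluded by default from the
complex I and overall burden tallies, from the SNV scan and from the variant
loads; otherwise it would appear as a perfect, and perfectly uninformative,
association. The exclusion removes the variant from all counters of the
affected categories — for m.11778G>A only the transition, non-synonymous
and rare/common counters can be affected in practice.

# The gene model and the seven-region partition

The gene model maps every rCRS position 1–16569 to exactly one of seven
functional regions: complex I (the seven ND genes), complex III (MT-CYB),
complex IV (the three CO genes), ATP synthase (MT-ATP6/8), rRNA, tRNA, and
non-coding (the origin-wrapping control region, 16024–16569 plus 1–576, and
the short intergenic spacers). Positions inside gene overlaps are assigned
deterministically to the feature that starts first, so ATP8/ATP6 positions
are tallied under ATP synthase and ND4L/ND4 positions under complex I; since
both members of each classic overlap share a region, the partition is
unambiguous there. The canonical annotation contains a third, single-base
coding overlap — the ATP6 terminator at 9207 coincides with the CO3 start
codon — which the same rule assigns to ATP synthase. Effect annotation at
overlap positions reports the protein change with respect to every covering
reading frame (`overlap_effects`), but each variant is counted once, in its
primary region.

Effects are computed by codon arithmetic under the vertebrate mitochondrial
genetic code (TGA = Trp, ATA = Met, AGA/AGG = stop), reverse-complementing
for the light-strand protein gene MT-ND6. Variants that fall in the one or
two dangling bases of a gene whose length is not a codon multiple (the
incomplete terminal codons completed by polyadenylation in vivo) have no
codon to translate; they are classified `rna-change` and therefore enter
Ts/Tv and rarity tallies but not NS/S tallies. This affects a handful of
positions genome-wide and no analysed site.

## The synthetic reference sequence

The package does not redistribute the rCRS sequence itself. The packaged
FASTA (`rcrs_synthetic.fasta`) is a deterministic synthetic stand-in built by
`build_synthetic_reference()`: real gene coordinates, strands and frames;
open reading frames for all 13 protein genes (internal stop codons repaired,
ATG start codons, the ATP6 TAA terminator at 9205–9207 overlapping the CO3
start); and the published reference alleles/codons pinned at every site used
by the bundled analyses — the primary mutation, the reported-association
variants and all marker-tree sites — so that every documented protein change
(p.Ala177Thr, p.Lys58=, p.Thr180=, p.Glu169=, p.Ala64Val, p.Met104Val,
p.Ala29Thr, p.Arg340His) arises from genuine codon translation at the real
coordinates. Everything that depends only on coordinates, frames and the
pinned sites behaves as with the true reference; base identity elsewhere is
pseudo-random, so annotating *real* genomes requires supplying a true rCRS
FASTA to `load_gene_model()`. The remaining fill uses heavy-strand base
composition (A 30.9%, C 31.3%, G 13.1%, T 24.7%) from a fixed internal seed,
independent of the user's RNG.

# Statistics

**Fisher exact test.** `fisher_exact_2x2()` implements the two-sided
point-probability ("minimum-likelihood") definition: the p-value sums the
hypergeometric probabilities of all tables with the observed margins whose
point probability does not exceed that of the observed table, with a 1e-7
relative tolerance for floating-point ties. This is the definition used by
the major commercial statistics packages, and it reproduces the published
desk-scale values exactly (e.g. (5,42,0,42) → 0.057; (6,41,0,42) → 0.028).
It always runs on raw counts — zero-cell corrections never touch the
p-value.

**Odds ratio and the Haldane–Anscombe correction.** When any cell of the 2×2
table is zero, 0.5 is added to *all four* cells before `OR = ad/bc`. The
all-cells variant (rather than correcting only the zero cell) is the
standard Haldane–Anscombe estimator and is confirmed by the published
corrected values it reproduces: (5,42,0,42) → 11.000 and (6,41,0,42) →
13.313.

**Woolf (logit) confidence interval.** `exp(ln OR ± z·SE)` with
`SE = √(1/a + 1/b + 1/c + 1/d)` over the (possibly corrected) cells and the
exact normal quantile (z = 1.959964 at 95%). Published bounds below ~10 are
matched to three decimals; large upper bounds to within 0.5% relative, which
absorbs the unknown rounding of the original software.

**t-tests.** `pooled_t_test()` works from summary statistics
(mean, SD, n per group) because variant-load comparisons are often published
only at that level. The default is the pooled-variance test
(df = n1+n2−2), which reproduces the published load p-values (0.295, 0.531)
from the published summaries; Welch is available via `var_equal = FALSE`.
Two degenerate groups with zero variance and equal means give t = 0, p = 1
by convention.

**Reconstructing cells from printed percentages.** Published tables print
group sizes and rounded percent frequencies. `counts_from_percent()` inverts
the rounding (`k = round(pct·n/100)`, half-up) and verifies that the
reconstructed count re-rounds to the printed percent, warning on
inconsistency rather than failing. All 19 tables in `lhon_fixture()` pass
this check and reproduce their published odds ratios to three decimals,
which validates the reconstruction end to end. The regional rare-variant
table is the one place raw cells are *not* uniquely recoverable from the
printed statistics, so the fixture stores the published statistics only.

**Multiple testing.** None is applied, matching standard practice in these
exploratory cohort studies; all p-values are reported as nominal.

# Haplogroup assignment

The external haplogroup services used in published studies do not document
their scoring, so `assign_haplogroup()` defines its own transparent
concordance score: for each tree node, `matched − λ·missing` over the
cumulative root-to-node defining variants, with λ = 0.5 by default; ties go
to the deeper node, then to the lexicographically smaller name. Positions on
an ignore list (mutational hotspots such as 16519, 309, 310) contribute
neither matches nor penalties — standard haplogroup-calling hygiene that
prevents spurious penalties at hypervariable sites. The score is validated
by construction-recovery: on synthetic cohorts with complete marker sets the
assignment recovers 100% of generating labels (an acceptance property), and
a brute-force exhaustive scorer over all nodes is kept as an independent
oracle in the tests.

The packaged mini-tree is an *rCRS-rooted scoring tree*, not the true human
phylogeny: the root is the rCRS baseline (haplogroup H, empty defining set)
and every other clade is expressed by the variants distinguishing it from
rCRS, accumulating along the path. Because rCRS itself sits inside
haplogroup H, clades that are phylogenetically ancestral to H appear here as
derived marker sets — the standard trick of rCRS-relative haplogroup
calling. The tree carries the 12 reporting labels of the motivating study
(B, H, HV, I, J, K, N, T, U, V, W, X) plus JT, U8 and U8b trunk nodes with K
under U8b; a `report` column maps trunk nodes to their reporting label
(U8/U8b → U), encoding the convention that a subject is reported as K only
when it carries the K-specific markers beyond U8b. Full Phylotree imports
are supported through the same TSV format.

# Rarity, heteroplasmy and scores

Rarity uses an inclusive cutoff: population frequency ≤ 0.5% is rare, above
is common. Variants absent from the frequency table are classed `unknown`
and excluded from rare/common tallies and spectrum denominators rather than
assumed rare — assuming rarity would inflate rare counts whenever the
frequency snapshot is incomplete. Frequencies are treated as per-allele
percentages.

The homoplasmy threshold defaults to 95%: callers in this setting report
mutant-allele fractions, and the highest fraction still reported as
heteroplasmic in the motivating data is 92%, so 95% separates the observed
heteroplasmic calls (70–92%) from homoplasmy without being tight against
either. It is configurable.

Pathogenicity scores live in [0,1] and enter as an external table (the
predictor itself is out of scope); both nucleotide keys (`m.9055G>A`) and
amino-acid keys (`p.Ala177Thr`) are accepted, nucleotide keys taking
precedence. Per-subject loads sum scores over non-synonymous variants
(total) or over scores strictly above 0.5 (threshold load). Non-synonymous
variants missing from the table are skipped with a warning by default
(`missing_score = "fail"` upgrades this to an error); the published analyses
give no policy, and silent skipping with a count in `n_unscored` keeps the
loads computable on partial tables.

# Burden tallies

`occurrence` mode counts every variant observation across subjects;
`unique` mode counts each distinct (position, alt) at most once per group —
"unique" is per group, matching the published per-group unique counts. The
rarity spectrum (rare/common shares per region) uses occurrence counts by
default, consistent with the Fisher inputs of the regional rare-variant
comparison; `mode = "unique"` switches it. When a burden contrast has an
empty exposure row in both groups (e.g. zero transversions among tRNA
variants in both), there is no 2×2 contrast and the result is reported as
n/a rather than forcing a degenerate test.

# The synthetic cohort generator

The generator's defaults *are* the study conditions: 47 patients and 42
controls; per-group haplogroup probabilities equal to the reported
12-haplogroup distribution; every patient carries m.11778G>A, homoplasmic
except with probability 4/47, in which case the level is uniform on 70–95%;
per-region expected variant counts per subject derived from the reported
per-group regional occurrence totals (e.g. complex I 6.55/5.40 per
patient/control, non-coding 8.30/7.19); transition probability 0.97
(overall Ts/Tv ≈ 33); non-synonymous probability 0.40 for coding variants
(reported NS fraction ≈ 245/611); scores Beta(2, 4). Per-region rare shares
follow the direction of the reported differences, with the two printed
values used exactly (complex IV 19% patients / 34% controls) and the
remainder set once at plausible magnitudes (complex I 0.20/0.26,
complex III 0.22/0.24, ATP synthase 0.25/0.25, rRNA 0.18/0.22, tRNA
0.10/0.35, non-coding 0.30/0.23).

Each cohort consumes a single pseudo-random stream seeded from the
configuration, in documented per-subject order (haplogroup → markers →
regional filler variants → scores → heteroplasmy), and restores the global
RNG state afterwards. Two design points matter for the recovery properties:

* **Marker sites are reserved.** Filler positions are drawn uniformly within
  each region *excluding* all marker-tree sites and the primary-mutation
  site, so haplogroup-defining variants appear only through the haplogroup
  draw. Without this, random filler can imitate another clade's markers and
  the planted label is no longer the mathematically correct call.
* **Rarity is steered at draw time.** A population frequency is one number
  per variant, so a variant first drawn as common cannot later be rare for
  the other group. The generator therefore decides the wanted class per
  occurrence (Bernoulli at the configured share) and redraws the candidate
  variant — up to 20 attempts — when an already-assigned frequency
  contradicts it. Realized per-occurrence classes are then independent
  Bernoulli draws at the configured share (up to a vanishing exhaustion
  probability), which is what the parameter-recovery acceptance check
  verifies at 500 subjects per group within three binomial standard errors.
  A side effect is that recurrent variants tend to be common and rare
  variants tend to be singletons — which is also how real population data
  behave.

What the generator does *not* emulate: linkage between non-marker variants
(filler sites are independent), realistic position-specific mutation spectra
beyond the Ts/Tv knob, sequencing error, indels or large deletions, and
nuclear modifiers. Passing tests on synthetic cohorts therefore validate the
pipeline's bookkeeping and statistics, not any biological claim about real
genomes; the published-table reconstructions are the contact point with real
data.

# Problem sizes and test design

The bundled checks run at sizes chosen to keep the whole suite comfortable
on a single CPU while leaving the statistical properties sharp: exhaustive
Fisher-vs-enumeration equality over all 2×2 tables with margins up to 15
(18,496 tables); parameter recovery at 500 subjects per group (≈29,000
variant observations); null-calibration over ≥1,000 per-variant Fisher tests
from replicate null cohorts at the study's 47/42 group sizes, asserting a
rejection rate ≤7% at nominal 0.05 (the exact test is conservative at these
counts, so the observed rate sits well below the nominal level). The
analysis scripts use a fixed seed (20200801) so their outputs are
reproducible; `run_pipeline()` produces byte-identical tables for identical
configurations, with timestamps confined to the log.

# Known limitations

* Indels, large deletions and structural variants are out of scope; inputs
  are single-nucleotide substitutions.
* The synthetic reference supports coordinate- and frame-faithful analysis
  of the bundled sites only; real-genome annotation needs the true rCRS.
* The mini-tree is coarse (reporting-level); sub-haplogroup strings such as
  "B4c1b2" are not reproduced.
* The TSV cohort format drops subjects with zero variants on a round trip
  (the VCF format keeps them as all-reference samples).
* Fisher p-values are nominal; no multiplicity control is applied.
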