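#!/usr/bin/env Rscript
# Step 1: generate the synthetic study cohort.
#
# Draws a case-control cohort under the study conditions (47 LHON patients
# carrying m.11778G>A, 42 controls; reported haplogroup distribution;
# per-region variant rates) and writes it through the package's TSV and VCF
# writers together with the generated population-frequency and
# pathogenicity-score tables, so the later steps exercise the file readers.

suppressPackageStartupMessages({
  library(mtassoc)
  library(readr)
})

out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = 20200801)
sim <- simulate_cohort(cfg)

message(sprintf("simulated %d patients / %d controls, %d variant observations",
                n_patients(sim$cohort), n_controls(sim$cohort),
                nrow(sim$cohort$variants)))
message(sprintf("%d distinct variants with population frequencies, %d scored",
                nrow(sim$frequencies), nrow(sim$scores)))

write_cohort_tsv(sim$cohort, file.path(out, "cohort.tsv"))
write_cohort_vcf(sim$cohort, file.path(out, "cohort.vcf.gz"))
write_tsv(sim$frequencies, file.path(out, "population_frequencies.tsv"))
write_tsv(sim$scores, file.path(out, "pathogenicity_scores.tsv"))
write_tsv(sim$truth, file.path(out, "planted_tallies.tsv"))
write_tsv(sim$cohort$subjects, file.path(out, "subjects.tsv"))

message("wrote cohort, frequency/score tables and planted tallies to ", out)
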