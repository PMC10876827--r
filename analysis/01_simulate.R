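#!/usr/bin/env Rscript
# Stage 1 — simulate the synthetic study.
#
# Builds the default pathology scenario: a 210-region mirrored atlas, 10
# glioma patients and 8 healthy controls, unilateral tumors with overlap
# fractions straddling the 12% inclusion boundary, elevated (peri)tumoral
# aperiodic offset, and offset-dependent loss of lower-alpha coupling.
# Epoch counts are reduced (5 patient / 4 control) relative to the emulated
# acquisition (15 / 8) to keep the demonstration run fast; pass
# --full-epochs to use the acquisition defaults.
#
# Writes the study (tables + one binary signal file per subject) under
# scratch/run/study/ and the input tables under results/.

library(gliodev)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1 && grepl("^[0-9]+$", args[1])) as.integer(args[1]) else 11L
full <- "--full-epochs" %in% args

study <- simulate_study(
  n_per_hemisphere = 105, n_patients = 10, n_hc = 8,
  n_epochs_patient = if (full) 15 else 5,
  n_epochs_hc = if (full) 8 else 4,
  seed = seed)

dir.create("results", showWarnings = FALSE)
write_study(study, "scratch/run/study")
write_table_tsv(study$cohort, "results/cohort.tsv")
write_table_tsv(study$overlaps, "results/tumor_overlaps.tsv")

n_peri <- sum(study$overlaps$overlap_fraction >= 0.12)
cat(sprintf("Simulated %d subjects (%d patients, %d HCs), %d regions.\n",
            nrow(study$cohort), sum(study$cohort$group == "patient"),
            sum(study$cohort$group == "HC"), nrow(study$atlas)))
cat(sprintf("Tumor overlaps: %d region-patient pairs >= 12%%, %d sub-threshold.\n",
            n_peri, sum(study$overlaps$overlap_fraction > 0 &
                          study$overlaps$overlap_fraction < 0.12)))
cat("Study written to scratch/run/study/\n")
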