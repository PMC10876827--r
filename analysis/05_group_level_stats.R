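#!/usr/bin/env Rscript
# Stage 5 — group-level statistics.
#
# Mann-Whitney U contrasts of patients' per-subject area means against HC
# whole-brain means (offset, CC, EC; FDR per measure/contrast family across
# 3 bands x 2 densities), within-patient Wilcoxon signed-rank tests of
# (peri)tumoral vs contralateral homologue means, and spatially constrained
# spin-test correlations between the group-mean raw offset map and the
# group-mean CC/EC maps (5000 rotations).
#
# Reads cached stage-2/3 features, writes results/area_tests.tsv,
# results/within_patient_tests.tsv, results/spin_tests.tsv.

library(gliodev)

study <- load_study("scratch/run/study")
offsets <- read_table_tsv("results/offsets.tsv")
metrics <- read_table_tsv("results/graph_metrics.tsv")

cfg <- pipeline_config(run_lmm = FALSE, run_subject_correlations = FALSE,
                       spin_n_perm = 5000, seed = study$seed)
res <- analyze_features(offsets, metrics, study, cfg)

for (nm in c("area_tests", "within_patient_tests", "spin_tests")) {
  if (!is.null(res[[nm]])) {
    write_table_tsv(res[[nm]], file.path("results", paste0(nm, ".tsv")))
  }
}

at <- res$area_tests
cat("Offset area contrasts vs HC whole brain:\n")
print(at[at$metric == "offset",
         c("contrast", "mean_dev", "sd_dev", "statistic", "p", "p_fdr")])
sig <- at[!is.na(at$p_fdr) & at$p_fdr < 0.05, ]
cat(sprintf("%d of %d area contrasts FDR-significant.\n", nrow(sig), nrow(at)))
sp <- res$spin_tests
cat(sprintf("Spin tests: %d maps correlated; %d with p_spin < 0.05.\n",
            nrow(sp), sum(sp$p_spin < 0.05)))
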