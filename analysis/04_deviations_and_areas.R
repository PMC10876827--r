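#!/usr/bin/env Rscript
# Stage 4 — control-referenced deviations and tumor areas.
#
# Standardizes every regional value (offset, CC, EC per band/density)
# against the healthy controls' regional mean and SD ("dev" values),
# assigns each patient's regions to (peri)tumoral / contralateral homologue
# / rest-of-brain / excluded areas via the 12% overlap rule, and summarizes
# per-subject area means.
#
# Reads results/offsets.tsv + results/graph_metrics.tsv, writes
# results/offset_dev.tsv, results/metric_dev.tsv, results/area_*.tsv.

library(gliodev)

study <- load_study("scratch/run/study")
offsets <- read_table_tsv("results/offsets.tsv")
metrics <- read_table_tsv("results/graph_metrics.tsv")

cfg <- pipeline_config(run_area_tests = FALSE, run_within_tests = FALSE,
                       run_spin = FALSE, run_lmm = FALSE,
                       run_subject_correlations = FALSE)
res <- analyze_features(offsets, metrics, study, cfg)

for (nm in c("offset_dev", "metric_dev", "area_assignments", "area_means")) {
  write_table_tsv(res[[nm]], file.path("results", paste0(nm, ".tsv")))
}

am <- res$area_means
off <- am[am$metric == "offset" & am$group == "patient", ]
cat("Patient offset_dev area means (subject-level):\n")
print(aggregate(mean_dev ~ area, off, function(x) round(mean(x, na.rm = TRUE), 3)))
cat(sprintf("HC whole-brain offset_dev mean: %.4f (0 by construction).\n",
            mean(am$mean_dev[am$metric == "offset" & am$group == "HC"])))
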