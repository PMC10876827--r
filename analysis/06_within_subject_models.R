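#!/usr/bin/env Rscript
# Stage 6 — within-subject models.
#
# Linear mixed models offset_dev ~ 1 + EC_dev + CC_dev with a random
# intercept per participant, fitted separately per group, frequency band and
# density (patients restricted to the rest-of-brain area), with Wald z
# inference, standardized betas and FDR across the non-intercept terms; plus
# per-subject Pearson correlations as a sensitivity check.
#
# Reads cached stage-2/3 features, writes results/lmm_results.tsv and
# results/subject_correlations.tsv.

library(gliodev)

study <- load_study("scratch/run/study")
offsets <- read_table_tsv("results/offsets.tsv")
metrics <- read_table_tsv("results/graph_metrics.tsv")

cfg <- pipeline_config(run_area_tests = FALSE, run_within_tests = FALSE,
                       run_spin = FALSE, seed = study$seed)
res <- analyze_features(offsets, metrics, study, cfg)

write_table_tsv(res$lmm_results, "results/lmm_results.tsv")
write_table_tsv(res$subject_correlations, "results/subject_correlations.tsv")

lmm <- res$lmm_results
pat_alpha <- lmm[lmm$group == "patient" & lmm$band == "lower_alpha" &
                   lmm$term != "(Intercept)", ]
cat("Patient lower-alpha fixed effects (rest of the brain):\n")
print(pat_alpha[, c("density", "term", "estimate", "ci_lo", "ci_hi",
                    "std_beta", "z", "p", "p_fdr")])
rs <- res$subject_correlations
cat("Mean per-subject r(offset_dev, CC_dev) by band (20% density):\n")
print(aggregate(r ~ band, rs[rs$metric == "cc" & rs$density == 0.2, ],
                function(x) round(mean(x, na.rm = TRUE), 3)))
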