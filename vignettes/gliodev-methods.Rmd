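---
title: "Methods: activity and network deviation mapping in glioma MEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activity and network deviation mapping in glioma MEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models and
procedures, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, the numerical choices made where the
design was open, and the known limitations. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. The analysis in one paragraph

For each subject we estimate, per cortical region, (i) the offset of the
aperiodic component of the MEG power spectrum — a proxy for regional
neuronal activity — and (ii) binary network metrics (local clustering
coefficient CC, eigenvector centrality EC) from phase-lag-index (PLI)
connectivity in the delta, theta and lower-alpha bands at 20% and 30%
network density. All regional values are z-scored against the
healthy-control (HC) cohort's regional mean and sample SD ("dev" values).
Patients' regions are partitioned by tumor overlap into (peri)tumoral
(overlap ≥ 12%), contralateral homologue, rest-of-brain (overlap = 0), and
excluded (0 < overlap < 12%). Group statistics compare patients'
per-subject area means against HC whole-brain means (Mann–Whitney U),
(peri)tumoral vs homologue within patients (Wilcoxon signed-rank),
group-mean raw maps of offset vs CC/EC under a spatially constrained spin
permutation test, and within-subject coupling of deviations via linear
mixed models (`offset_dev ~ 1 + EC_dev + CC_dev + (1 | subject)`), with
Benjamini–Hochberg FDR per measure/contrast family across the 3 bands × 2
densities (for the mixed models: across all non-intercept terms of a
group's band × density fits).

## 2. Spectral model

Power spectra use Welch's method with a Hamming window: segments of 2048
samples (≈ 0.61 Hz resolution at 1250 Hz) with 50% overlap, one-sided,
normalized by the window power so the integrated PSD approximates the
signal variance; per-epoch spectra are averaged arithmetically. The
segment length is a package default, not a quantity fixed by the emulated
study: 2048 samples resolves the delta band with ≥ 5 bins while averaging
3 segments per 4096-sample epoch.

The aperiodic model is `L(F) = b − log10(k + F^x)` fitted to log10 power
over 0.5–45 Hz (the broadband filter range). The default mode pins the
knee at `k = 0`, making the model linear in `log10 F`; a knee mode
(nonlinear least squares with bounded parameters and multiple restarts,
Nelder–Mead fallback) is available because the printed formula includes
`k`. Oscillatory peaks are handled by a two-pass scheme rather than a full
peak-Gaussian decomposition (explicitly out of scope): after an initial
fit, points whose residual exceeds one SD of the 2.5%-trimmed residuals
are flagged as peak candidates and the model is refitted on the remaining
points. R² is reported on the unflagged (aperiodic) points. The exponent
is clamped at 0 (an increasing aperiodic spectrum is reported as flat);
the clamp preserves the exact scaling equivariance `power × 10^c ⇒ b + c`.

Known estimator properties (measured by the tests): exact recovery on
noiseless power laws; offset bias ≲ 0.03 log10 units and SD ≈ 0.05 per
region at 15 epochs of stochastic data; one-sided peak flagging trims the
upper noise tail, which is the main residual bias source.

## 3. Connectivity and graph model

Band-pass filtering zeroes all FFT bins outside `[f_lo, f_hi]`; band edges
are inclusive on both sides, so 4 Hz and 8 Hz belong to two bands,
mirroring the printed overlapping band definitions. The filter is an
orthogonal projection (idempotent). Phases come from the analytic signal
(frequency-domain Hilbert transform), computed per epoch after per-epoch
filtering; no edge trimming is applied inside the pipeline (the emulated
study states none) — quadrature-pair *tests* exclude 5% edges, in the test
harness only.

`PLI = |⟨sign(sin Δφ)⟩|` is computed per epoch and averaged over epochs
(averaging PLI values, not phase statistics). A finite-sample property
matters at this epoch length: for *uncoupled* band-limited noise the PLI
does not vanish — a 2-Hz-wide band at 3.27 s yields only ~7 independent
phase samples, so the noise floor sits near 0.3, and epoch averaging
shrinks its variance but not its mean. Tests therefore assert planted
couplings against that floor, and — importantly — the floor depends on the
number of averaged epochs, which has a design consequence discussed in §6.

Proportional thresholding keeps the `round(density · n(n−1)/2)` strongest
upper-triangle weights (halves away from zero; 4389 edges at 20% of 210
nodes), with ties broken by ascending (i, j) order so outputs are
bit-reproducible and the 20% edge set nests inside the 30% set. CC is the
triangle fraction `2Tᵢ/(kᵢ(kᵢ−1))` (0 when degree < 2). EC is the
principal eigenvector of the adjacency, by power iteration from the
uniform vector, normalized to unit Euclidean norm; iteration runs on
`A + I` — same eigenvectors, strictly positive spectrum — because plain
power iteration oscillates on bipartite components (a star graph already
fails). Disconnected graphs are handled on the full adjacency; the
eigenvector then concentrates on the component with the largest spectral
radius and isolated nodes receive ~0.

## 4. Deviations, areas, statistics

Standardization uses the sample SD (n−1) of the HC cohort per region, so
the HC cohort standardized against itself has regional mean 0 and SD
exactly 1, and the pooled HC mean is exactly 0. Zero HC SD is an error in
`standardize_to_hc()`; the pipeline pre-filters such regions per stratum
(recording them in `dropped_regions`) because a region that is constant
across controls carries no normative information — at full cohort sizes
this path is never taken.

The unit of observation for the area tests is the per-subject area mean
(the U statistics of the emulated study are consistent with subject-level
comparisons, and pooled-region tests would inflate n by two orders of
magnitude); pooled-region testing remains available via
`unit_of_observation = "pooled_regions"`. Regions with 0 < overlap < 12%
belong to no area (literal reading of "0% tumor overlap" for
rest-of-brain). Patients whose (peri)tumoral set is empty or bilateral are
excluded from tumor-referenced analyses only; their rest-of-brain data
stay in.

The spin test draws one Haar-random rotation per permutation, applies it
to left-hemisphere centroids and its sagittal mirror to the right, and
reassigns each rotated centroid to the nearest original centroid within
its hemisphere (duplicates allowed — the original spherical-rotation
formulation). A distance-greedy bijective variant is available since the
cited implementation is unspecified. p = (1 + #{|r_null| ≥ |r_obs|}) /
(1 + n_perm), never below 1/(n_perm+1). Calibration under independent maps
is verified by a Kolmogorov–Smirnov test in the acceptance suite.

Mixed models follow the reading in which `offset_dev` is the response and
`EC_dev`, `CC_dev` the predictors (the emulated study's prose and its
table caption disagree; the caption's reading is implemented). Estimation
is REML via lme4 with Wald z inference; standardized betas come from a
refit on variables z-scored across included observations; singular fits
are flagged, not hidden. The FDR family for the mixed models spans the
non-intercept terms of all band × density fits within a group — with 12
p-values this reproduces the adjusted values printed by the emulated
study's within-subject table.

## 5. The synthetic world

The generator's defaults are the stated acquisition: 210 regions (105 per
hemisphere, mirrored through the sagittal plane), 1250 Hz sampling,
4096-sample epochs (3.2768 s — the power-of-two length matching the
printed 3.27 s), 15 epochs per patient and 8 per control.

**Aperiodic noise** is white Gaussian noise shaped in the frequency domain
by the square root of the target power law, so the expected one-sided PSD
equals `10^b/(k + F^x)` exactly — no AR-model ambiguity. Synthesis extends
slightly beyond the 0.5–45 Hz analysis band (half an octave below, 1.5 Hz
above) so that spectral-estimation kernels centered on the edge bins see
power-law content on both sides, as a real acquisition filter roll-off
would allow; a brick-wall edge exactly at 0.5 Hz depresses the first Welch
bin by ~0.3 log10 units and would bias every offset fit.

**Coupling** is carried by shared narrow-band oscillators: each spatial
module (7 per hemisphere, nearest-seed partition of the centroids,
mirrored) owns one sinusoid at a module-specific carrier in 8.2–9.8 Hz;
each member region receives it with a fixed per-region lag (|lag| in
0.15π–0.85π, avoiding 0 and π) and a per-region coupling strength in
[0, 1] scaling the amplitude. At high SNR a coupled pair's phase
difference is the constant lag difference, so PLI → 1; strength modulates
PLI monotonically (a tested invariant). Pairwise couplings
(`pair_coupling()`) are two-member oscillators.

**Free parameters** (the emulated study states no oscillation amplitudes
or SNR): baseline offset 1.0 log10 units, exponent 1.5, between-subject
offset SD 0.15 and region-level SD 0.10 (HC regional SD ≈ 0.18),
oscillator amplitude 4.0, baseline strengths U(0.6, 0.95). These were
chosen once as a plausible MEG-like regime and not revisited.

**Pathology scenario** (default on): offsets are elevated by +0.28 in
regions with overlap ≥ 12% and +0.068 elsewhere — landing the expected
deviations near +1.56 and +0.38, the printed ordering — and a region's
lower-alpha coupling strength shrinks with its positive offset excess
(factor `1 − 0.9·excess/0.3`), planting the negative within-subject
offset–clustering association. Tumors are unilateral, spatially contiguous
(a seed region and its nearest neighbours), with overlap fractions
spanning (0.05, 0.9) and one region forced into (0, 0.12) so the inclusion
boundary is always exercised.

**What the generator does not emulate** — hence what a green test does not
establish: no forward/inverse modeling or source leakage (real PLI
estimates fight volume conduction; ours only face finite samples), no
anatomically realistic atlas geometry or volumetric masks, no planted
group-level spatial correlation between raw offset and connectivity maps
(the default world's group-level spin tests are null), no delta/theta
coupling structure (those networks are noise-driven), and no
clinical covariates.

## 6. Caveats found while validating

*Unequal epoch counts are a confound for PLI-derived metrics.* The PLI
noise floor depends on the number of averaged epochs, so patients (15
epochs) and controls (8) differ systematically in thresholded-network
statistics even with no planted pathology: in a 20-seed "no effects"
calibration with 3 vs 2 epochs, the rest-of-brain clustering contrast —
the largest averaging area, hence the most sensitive — rejected far above
nominal. With epoch counts equalized the family discovery rate returns to
nominal (12/140 at the 0.05 level). The package's null-calibration test
therefore equalizes epoch counts; the caveat applies equally to the real
design it emulates.

*Eigenvector centrality at reduced scale.* On modular-plus-noise binary
graphs the principal eigenvector is dominated by the random backbone, and
its response to the planted coupling loss is small with unstable sign
across densities at the reduced cohort size. The end-to-end acceptance
check asserts the planted offset–clustering coupling (negative CC_dev
slopes at both densities) and reports EC without asserting its sign.

*Degenerate EC deviations.* Winner-take-all concentration can make a
region's EC nearly constant across controls, producing huge dev values for
that region; the mixed models tolerate this (it inflates one predictor's
scale), but it is the main reason EC_dev distributions are heavy-tailed at
small scale.

## 7. Reproducibility

Every stochastic function takes an explicit seed; child seeds are derived
with a fixed linear-congruential step and stay within 32-bit range. The
pipeline streams one subject's signal at a time (a full-size subject is
~100 MB), caches per-stage tables as TSV, and writes a manifest (config
echo, MD5, seeds, package version) sufficient to re-execute a run
bit-identically; reruns produce byte-identical tables. Configuration is a
plain JSON-serializable list (`pipeline_config()`); JSON was chosen over
YAML because the target environment ships no R YAML parser.
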