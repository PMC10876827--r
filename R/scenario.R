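# Study-level synthetic scenarios: assemble atlas, cohort, tumor overlaps and
# per-subject ground truth for the default pathology scenario (elevated
# (peri)tumoral offset plus offset-dependent loss of lower-alpha coupling)
# and for a null scenario with no planted effects.

#' Parameters of the synthetic study scenarios
#'
#' All values are fixed properties of the emulated world. The aperiodic
#' baseline (`offset0` 1.0 log10 power units, exponent 1.5) with
#' between-subject SD 0.15 and region-level SD 0.10 gives a healthy-control
#' regional offset SD of ~0.18, so the planted patient elevations of +0.28
#' ((peri)tumoral, overlap >= 0.12) and +0.068 (everywhere else) land near
#' deviation (z) values of ~1.56 and ~0.38, the ordering the pipeline is
#' meant to detect. Lower-alpha (8-10 Hz) connectivity is carried by one
#' shared oscillator per spatial module (7 modules per hemisphere, mirrored),
#' with per-region lags and coupling strengths; in patients a region's
#' coupling strength shrinks with its positive offset excess
#' (`coupling_gamma`), planting a negative within-subject association between
#' offset deviation and lower-alpha network metrics.
#'
#' @param pathology logical; `FALSE` yields the null scenario (no planted
#'   elevation, no offset-coupling link).
#' @return Named list of scenario parameters.
#' @export
scenario_params <- function(pathology = TRUE) {
  list(
    pathology = isTRUE(pathology),
    offset0 = 1.0,            # baseline aperiodic offset, log10 power units
    exponent0 = 1.5,          # baseline aperiodic exponent
    subject_sd = 0.15,        # between-subject offset SD
    region_sd = 0.10,         # region x subject offset noise SD
    exponent_sd = 0.05,
    delta_peritumoral = 0.28, # offset elevation, overlap >= 0.12
    delta_other = 0.068,      # offset elevation elsewhere in patients
    coupling_gamma = 0.9,     # strength loss per 0.3 log10 units offset excess
    n_modules_per_hemisphere = 7L,
    carrier_range = c(8.2, 9.8),  # Hz, module carriers inside lower alpha
    osc_amplitude = 4.0,
    strength_range = c(0.6, 0.95),
    strength_subject_sd = 0.05,
    lag_range = c(0.15 * pi, 0.85 * pi),
    tumor_core_range = c(3L, 8L),
    tumor_fraction_range = c(0.05, 0.9)
  )
}

# Spatially contiguous modules: k seed regions per hemisphere, other regions
# join the nearest seed; right hemisphere mirrors the left partition.
module_partition <- function(atlas, n_modules_per_hemisphere, seed) {
  cen <- atlas_centroids(atlas)
  left <- which(atlas$hemisphere == "left")
  k <- min(n_modules_per_hemisphere, length(left))
  seeds <- with_seed(seed, sample(left, k))
  d <- cen[left, , drop = FALSE] %*% t(cen[seeds, , drop = FALSE])
  mod <- integer(nrow(atlas))
  mod[left] <- max.col(d, ties.method = "first")
  hom <- atlas$homologue_id[left] + 1L
  mod[hom] <- mod[left] + k             # mirrored modules, separate oscillators
  mod
}

#' Assemble a complete synthetic study
#'
#' Builds the atlas, cohort, per-patient tumor-overlap tables and per-subject
#' ground truth for either the default pathology scenario or the null
#' scenario (see [scenario_params()]). Signals are not generated here — they
#' can be large — but by [subject_signal()] on demand, so pipelines can
#' stream subject by subject.
#'
#' @param n_per_hemisphere regions per hemisphere (default 105 -> 210).
#' @param n_patients,n_hc group sizes.
#' @param n_epochs_patient,n_epochs_hc epochs per subject (defaults 15 / 8).
#' @param seed integer master seed; subject seeds derive from it.
#' @param params scenario parameter list from [scenario_params()].
#' @param sampling_rate,epoch_length acquisition settings.
#' @return A study bundle: list with `atlas`, `cohort` (subjects table),
#'   `sampling_rate`, `epoch_length`, `overlaps` (long per-patient table),
#'   `ground_truth` (named list per subject), `params`, `seed`.
#' @export
simulate_study <- function(n_per_hemisphere = 105L, n_patients = 10L, n_hc = 8L,
                           n_epochs_patient = 15L, n_epochs_hc = 8L,
                           seed = 1L, params = scenario_params(),
                           sampling_rate = 1250, epoch_length = 4096L) {
  atlas <- make_atlas(n_per_hemisphere, seed = derive_seed(seed, 1L))
  spec <- cohort_spec(n_patients, n_hc, n_epochs_patient, n_epochs_hc,
                      sampling_rate, epoch_length)
  n <- nrow(atlas)
  p <- params

  mod <- module_partition(atlas, p$n_modules_per_hemisphere, derive_seed(seed, 2L))
  n_mod <- max(mod)
  base <- with_seed(derive_seed(seed, 3L), list(
    carriers = runif(n_mod, p$carrier_range[1], p$carrier_range[2]),
    lags = runif(n, p$lag_range[1], p$lag_range[2]) * sample(c(-1, 1), n, TRUE),
    strength = runif(n, p$strength_range[1], p$strength_range[2])
  ))

  overlaps <- NULL
  ground_truth <- list()
  for (s in seq_len(nrow(spec$subjects))) {
    entry <- spec$subjects[s, ]
    sseed <- derive_seed(seed, 100L + s)
    is_patient <- entry$group == "patient"

    delta <- numeric(n)
    if (is_patient) {
      ov <- make_tumor_overlap(
        atlas, seed = derive_seed(sseed, 1L),
        n_core_regions = with_seed(derive_seed(sseed, 2L),
                                   sample(p$tumor_core_range[1]:p$tumor_core_range[2], 1L)),
        fraction_range = p$tumor_fraction_range)
      overlaps <- rbind(overlaps,
                        cbind(subject_id = entry$subject_id, ov,
                              stringsAsFactors = FALSE))
      if (p$pathology) {
        delta <- ifelse(ov$overlap_fraction >= 0.12,
                        p$delta_peritumoral, p$delta_other)
      }
    }

    gt <- with_seed(derive_seed(sseed, 3L), {
      u <- rnorm(1L, 0, p$subject_sd)
      e <- rnorm(n, 0, p$region_sd)
      strength <- pmin(1, pmax(0, base$strength + rnorm(n, 0, p$strength_subject_sd)))
      if (is_patient && p$pathology) {
        excess <- pmax(0, delta + e)
        strength <- strength * pmax(0, 1 - p$coupling_gamma * excess / 0.3)
      }
      oscillators <- lapply(seq_len(n_mod), function(m) {
        idx <- which(mod == m)
        list(freq = base$carriers[m], amplitude = p$osc_amplitude,
             members = data.frame(region_id = atlas$region_id[idx],
                                  lag = base$lags[idx],
                                  strength = strength[idx]))
      })
      list(offset = p$offset0 + u + e + delta,
           exponent = pmax(0.1, p$exponent0 + rnorm(n, 0, p$exponent_sd)),
           knee = 0,
           oscillators = oscillators)
    })
    ground_truth[[entry$subject_id]] <- gt
  }

  list(atlas = atlas, cohort = spec$subjects,
       sampling_rate = spec$sampling_rate, epoch_length = spec$epoch_length,
       overlaps = overlaps, ground_truth = ground_truth,
       params = p, seed = seed)
}

#' Generate one subject's signal from a study bundle
#'
#' @param study study bundle from [simulate_study()].
#' @param subject_id subject identifier present in `study$cohort`.
#' @return Epoched-signal object (see [simulate_subject()]).
#' @export
subject_signal <- function(study, subject_id) {
  row <- match(subject_id, study$cohort$subject_id)
  if (is.na(row)) stop_arg("unknown subject_id '%s'", subject_id)
  entry <- list(subject_id = subject_id,
                group = study$cohort$group[row],
                n_epochs = study$cohort$n_epochs[row],
                sampling_rate = study$sampling_rate,
                epoch_length = study$epoch_length)
  simulate_subject(study$atlas, entry, study$ground_truth[[subject_id]],
                   seed = derive_seed(study$seed, 5000L + row))
}
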