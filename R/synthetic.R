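# Synthetic-data generator: epoched regional time series with known aperiodic
# and phase-coupling ground truth, plus tumor-overlap tables.

#' Cohort specification defaults
#'
#' Acquisition defaults used throughout the pipeline: 1250 Hz sampling,
#' 4096-sample epochs (3.2768 s, the power-of-two length matching the
#' printed ~3.27 s epochs), 15 epochs per patient and 8 per control.
#'
#' @param n_patients,n_hc number of subjects per group.
#' @param n_epochs_patient,n_epochs_hc epochs per subject by group.
#' @param sampling_rate sampling frequency in Hz.
#' @param epoch_length epoch length in samples.
#' @return A list with a `subjects` data.frame (`subject_id`, `group`,
#'   `n_epochs`) and the acquisition fields.
#' @export
cohort_spec <- function(n_patients, n_hc,
                        n_epochs_patient = 15L, n_epochs_hc = 8L,
                        sampling_rate = 1250, epoch_length = 4096L) {
  stopifnot(n_patients >= 0, n_hc >= 0, n_epochs_patient >= 1, n_epochs_hc >= 1,
            sampling_rate > 0, epoch_length >= 2)
  subjects <- data.frame(
    subject_id = c(sprintf("pat%03d", seq_len(n_patients)),
                   sprintf("hc%03d", seq_len(n_hc))),
    group = rep(c("patient", "HC"), c(n_patients, n_hc)),
    n_epochs = rep(c(as.integer(n_epochs_patient), as.integer(n_epochs_hc)),
                   c(n_patients, n_hc)),
    stringsAsFactors = FALSE
  )
  list(subjects = subjects, sampling_rate = sampling_rate,
       epoch_length = as.integer(epoch_length))
}

#' Describe a shared-oscillator coupling between two regions
#'
#' A coupled pair shares one narrow-band oscillator: both regions receive the
#' same sinusoid (fresh random initial phase each epoch) but region `j` with a
#' constant phase lag. At high signal-to-noise ratio the phase lag index of
#' the pair tends to 1 for lags away from 0 and +/- pi.
#'
#' @param region_i,region_j 0-based region ids.
#' @param freq carrier frequency in Hz.
#' @param lag phase lag in radians applied to `region_j`.
#' @param strength coupling strength in `[0, 1]`, scales the oscillator
#'   amplitude.
#' @param amplitude base oscillator amplitude (signal units).
#' @return An oscillator description usable in `ground_truth$oscillators`.
#' @export
pair_coupling <- function(region_i, region_j, freq, lag, strength = 1,
                          amplitude = 4) {
  list(freq = freq, amplitude = amplitude,
       members = data.frame(region_id = c(region_i, region_j),
                            lag = c(0, lag),
                            strength = c(strength, strength)))
}

validate_ground_truth <- function(ground_truth, n_regions) {
  gt <- ground_truth
  stopifnot(length(gt$offset) == n_regions, length(gt$exponent) == n_regions)
  if (is.null(gt$knee)) gt$knee <- 0
  if (is.null(gt$oscillators)) gt$oscillators <- list()
  for (osc in gt$oscillators) {
    if (any(osc$members$strength < 0 | osc$members$strength > 1)) {
      stop_arg("coupling strength must lie in [0, 1]")
    }
    if (any(!osc$members$region_id %in% 0:(n_regions - 1L))) {
      stop_arg("oscillator references a region id outside the atlas")
    }
  }
  gt
}

#' Simulate one subject's epoched regional time series
#'
#' Each region/epoch is aperiodic noise whose expected one-sided power
#' spectral density follows `10^b / (k + f^x)` over the 0.5-45 Hz broadband
#' range (white Gaussian noise shaped in the frequency domain by the square
#' root of the target power law; content outside the band is zeroed, matching
#' a 0.5-45 Hz acquisition filter). Oscillators from the ground truth are
#' added on top: each oscillator draws a fresh uniform initial phase per
#' epoch and injects `strength * amplitude * cos(2 pi f t + theta - lag)`
#' into each member region. Deterministic given `seed`.
#'
#' @param atlas atlas data.frame from [make_atlas()].
#' @param cohort_entry list with `subject_id`, `group`, `n_epochs`,
#'   `sampling_rate`, `epoch_length` (see [cohort_spec()]).
#' @param ground_truth list with per-region `offset` (log10 power units),
#'   `exponent`, optional scalar/vector `knee` (default 0), and optional
#'   `oscillators` (see [pair_coupling()]).
#' @param seed integer seed.
#' @param band_limits frequency band retained by the synthetic acquisition
#'   filter, in Hz.
#' @return An epoched-signal object: list with `data` (array regions x
#'   epochs x samples), `sampling_rate`, `subject_id`, `group`.
#' @export
simulate_subject <- function(atlas, cohort_entry, ground_truth, seed,
                             band_limits = c(0.5, 45)) {
  validate_atlas(atlas)
  n <- nrow(atlas)
  gt <- validate_ground_truth(ground_truth, n)
  n_epochs <- as.integer(cohort_entry$n_epochs)
  fs <- cohort_entry$sampling_rate
  N <- as.integer(cohort_entry$epoch_length)
  stopifnot(n_epochs >= 1, fs > 0, N >= 2)

  knee <- rep(gt$knee, length.out = n)
  freqs <- (0:(N %/% 2)) * fs / N
  # Synthesize slightly beyond the analysis band so that spectral-estimation
  # kernels centered on the edge bins (0.5 Hz, 45 Hz) still see power-law
  # content on both sides, as a real acquisition filter roll-off would allow.
  lo <- band_limits[1] / 2
  hi <- min(fs / 2, band_limits[2] + 1.5)
  in_band <- freqs >= lo & freqs <= hi & freqs > 0
  # target one-sided PSD per region x frequency bin
  psd <- matrix(0, n, length(freqs))
  for (r in seq_len(n)) {
    psd[r, in_band] <- 10^gt$offset[r] / (knee[r] + freqs[in_band]^gt$exponent[r])
  }
  amp <- sqrt(psd * fs * N / 2)          # spectral amplitude so E[periodogram] = psd
  tt <- (0:(N - 1)) / fs

  out <- array(0, dim = c(n, n_epochs, N))
  with_seed(seed, {
    nb <- N %/% 2 - 1L                    # strictly positive, non-Nyquist bins
    for (e in seq_len(n_epochs)) {
      # complex Gaussian spectrum, conjugate-symmetric; DC and Nyquist zeroed
      re <- matrix(rnorm(n * nb), n, nb)
      im <- matrix(rnorm(n * nb), n, nb)
      spec <- matrix(0 + 0i, N, n)
      spec[2:(N %/% 2), ] <- t((re + 1i * im) / sqrt(2) * amp[, 2:(N %/% 2)])
      spec[seq(N, N %/% 2 + 2L), ] <- Conj(spec[2:(N %/% 2), ])
      x <- Re(mvfft(spec, inverse = TRUE)) / N   # samples x regions
      x <- t(x)
      for (osc in gt$oscillators) {
        theta <- runif(1L, 0, 2 * pi)
        m <- osc$members
        for (q in seq_len(nrow(m))) {
          if (m$strength[q] <= 0) next
          ridx <- m$region_id[q] + 1L
          x[ridx, ] <- x[ridx, ] +
            m$strength[q] * osc$amplitude * cos(2 * pi * osc$freq * tt + theta - m$lag[q])
        }
      }
      out[, e, ] <- x
    }
  })
  structure(list(data = out, sampling_rate = fs,
                 subject_id = cohort_entry$subject_id,
                 group = cohort_entry$group),
            class = "gliodev_signal")
}

#' Generate a synthetic tumor-overlap table
#'
#' Selects a spatially contiguous set of same-hemisphere regions (a seed
#' region and its nearest neighbours) as the tumor core and assigns overlap
#' fractions spanning `fraction_range`, decreasing with distance from the
#' seed. When the lower end of the range is below 0.12 the most peripheral
#' core region is forced into (0, 0.12), so the table always exercises the
#' ">= 12% overlap" inclusion boundary. All non-core regions get exactly 0.
#'
#' @param atlas atlas data.frame.
#' @param seed integer seed.
#' @param n_core_regions number of regions with nonzero overlap (>= 1).
#' @param fraction_range numeric length 2, range of overlap fractions.
#' @param hemisphere `"left"`, `"right"`, or `NULL` to pick at random.
#' @return data.frame(`region_id`, `overlap_fraction`), one row per region.
#' @export
make_tumor_overlap <- function(atlas, seed, n_core_regions = 5L,
                               fraction_range = c(0.05, 0.9),
                               hemisphere = NULL) {
  validate_atlas(atlas)
  if (n_core_regions < 1) stop_arg("n_core_regions must be >= 1")
  if (length(fraction_range) != 2L || any(fraction_range < 0) ||
      any(fraction_range > 1) || fraction_range[1] > fraction_range[2]) {
    stop_arg("fraction_range must be an increasing pair within [0, 1]")
  }
  n <- nrow(atlas)
  frac <- numeric(n)
  with_seed(seed, {
    hemi <- if (is.null(hemisphere)) sample(c("left", "right"), 1L) else hemisphere
    cand <- which(atlas$hemisphere == hemi)
    n_core <- min(as.integer(n_core_regions), length(cand))
    seed_region <- sample(cand, 1L)
    cen <- atlas_centroids(atlas)
    d <- sqrt(colSums((t(cen[cand, , drop = FALSE]) - cen[seed_region, ])^2))
    core <- cand[order(d)][seq_len(n_core)]           # contiguous: nearest first
    f <- seq(fraction_range[2], fraction_range[1], length.out = n_core)
    if (n_core > 2L) {
      mid <- 2:(n_core - 1L)
      gap <- diff(fraction_range) / max(1L, n_core - 1L)
      f[mid] <- pmin(fraction_range[2],
                     pmax(fraction_range[1], f[mid] + runif(length(mid), -gap, gap) / 3))
      f[mid] <- sort(f[mid], decreasing = TRUE)
    }
    if (fraction_range[1] < 0.12 && n_core > 1L) {
      f[n_core] <- runif(1L, max(fraction_range[1], 0.12 / 10), 0.119)
    }
    frac[core] <- f
  })
  data.frame(region_id = atlas$region_id, overlap_fraction = frac,
             stringsAsFactors = FALSE)
}
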