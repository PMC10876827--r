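# Connectivity module: FFT band-pass filtering, analytic-signal phase, and
# epoch-averaged phase lag index (PLI) adjacency matrices.

#' Default frequency bands
#'
#' Delta (0.5-4 Hz), theta (4-8 Hz) and lower alpha (8-10 Hz). Band edges are
#' inclusive on both sides, so boundary bins (4 Hz, 8 Hz) belong to two
#' bands, mirroring the printed overlapping band edges.
#'
#' @return Named list of `list(name, f_lo, f_hi)`.
#' @export
default_bands <- function() {
  list(
    delta = list(name = "delta", f_lo = 0.5, f_hi = 4),
    theta = list(name = "theta", f_lo = 4, f_hi = 8),
    lower_alpha = list(name = "lower_alpha", f_lo = 8, f_hi = 10)
  )
}

#' FFT-based band-pass filter
#'
#' Real FFT of the epoch; bins with frequency in `[f_lo, f_hi]` (inclusive)
#' are retained, all others — including DC — are zeroed; inverse transform.
#' The filter is an orthogonal projection, hence idempotent.
#'
#' @param x numeric vector (one epoch) or regions x samples matrix.
#' @param sampling_rate sampling frequency in Hz.
#' @param band list with `f_lo`, `f_hi` (see [default_bands()]).
#' @return Filtered signal, same shape as `x`.
#' @export
bandpass_fft <- function(x, sampling_rate, band) {
  if (band$f_lo >= band$f_hi) stop_arg("band must have f_lo < f_hi")
  if (band$f_hi > sampling_rate / 2) {
    stop_arg("band upper edge %.3g Hz exceeds Nyquist %.3g Hz",
             band$f_hi, sampling_rate / 2)
  }
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, nrow = 1L) else x
  N <- ncol(m)
  fr <- c(0:(N %/% 2), -((N - N %/% 2 - 1L):1L)) * sampling_rate / N
  keep <- abs(fr) >= band$f_lo & abs(fr) <= band$f_hi
  X <- mvfft(t(m))
  X[!keep, ] <- 0 + 0i
  out <- t(Re(mvfft(X, inverse = TRUE)) / N)
  if (vec) drop(out) else out
}

#' Instantaneous phase via the analytic signal
#'
#' Frequency-domain Hilbert transform: positive-frequency components doubled,
#' negative zeroed; the phase is the argument of the resulting analytic
#' signal, in (-pi, pi].
#'
#' @param x numeric vector (one filtered epoch) or regions x samples matrix.
#' @return Phase series, same shape as `x`.
#' @export
instantaneous_phase <- function(x) {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, nrow = 1L) else x
  if (any(apply(m, 1L, function(r) all(r == 0)))) {
    stop_arg("instantaneous phase is undefined for an all-zero signal")
  }
  N <- ncol(m)
  h <- numeric(N)
  h[1L] <- 1
  if (N %% 2L == 0L) {
    h[N %/% 2 + 1L] <- 1
    h[2:(N %/% 2)] <- 2
  } else {
    h[2:((N + 1L) %/% 2)] <- 2
  }
  Z <- mvfft(mvfft(t(m)) * h, inverse = TRUE) / N
  out <- t(Arg(Z))
  if (vec) drop(out) else out
}

#' Phase lag index of one region pair for one epoch
#'
#' `PLI = | mean_t sign( sin(phi_i(t) - phi_j(t)) ) |` with `sign(0) = 0`.
#' Zero for identical (or zero-lag coupled) phase series, 1 for a constant
#' nonzero lag; insensitive to amplitude by construction.
#'
#' @param phases_i,phases_j numeric phase vectors of equal length (radians).
#' @return PLI value in `[0, 1]`.
#' @export
pli_epoch <- function(phases_i, phases_j) {
  if (length(phases_i) != length(phases_j)) {
    stop_arg("phase series must have equal length")
  }
  abs(mean(sign(sin(phases_i - phases_j))))
}

#' Epoch-averaged PLI adjacency matrix
#'
#' Per-epoch PLI over all region pairs (compiled kernel), arithmetic mean
#' over epochs. Symmetric with zero diagonal.
#'
#' @param phases list over epochs of regions x samples phase matrices.
#' @param band band definition attached as metadata (optional).
#' @return Connectivity object: list with `values` (n x n matrix), `band`,
#'   `n_epochs_averaged`.
#' @export
pli_matrix <- function(phases, band = NULL) {
  if (length(phases) < 1L) stop_arg("at least one epoch is required")
  acc <- NULL
  for (ph in phases) {
    m <- pli_phase_matrix_cpp(ph)
    acc <- if (is.null(acc)) m else acc + m
  }
  structure(list(values = acc / length(phases), band = band,
                 n_epochs_averaged = length(phases)),
            class = "gliodev_connectivity")
}

#' Band-specific PLI connectivity for one subject
#'
#' Filters every epoch into the band, extracts analytic-signal phases, and
#' averages per-epoch PLI matrices.
#'
#' @param signal epoched-signal object.
#' @param band band definition (see [default_bands()]).
#' @return Connectivity object (see [pli_matrix()]).
#' @export
subject_connectivity <- function(signal, band) {
  d <- signal$data
  n <- dim(d)[1L]; n_epochs <- dim(d)[2L]; N <- dim(d)[3L]
  phases <- vector("list", n_epochs)
  for (e in seq_len(n_epochs)) {
    m <- d[, e, , drop = FALSE]
    dim(m) <- c(n, N)
    filt <- bandpass_fft(m, signal$sampling_rate, band)
    phases[[e]] <- instantaneous_phase(filt)
  }
  pli_matrix(phases, band = band)
}
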