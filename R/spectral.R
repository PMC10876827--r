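# Spectral module: Welch power spectral density (Hamming window) and fitting
# of the aperiodic model L(F) = b - log10(k + F^x) to the log10 power
# spectrum. The offset b is the pipeline's proxy for regional neuronal
# activity.

hamming_window <- function(L) {
  0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))
}

#' Welch power spectral density of one epoch
#'
#' Splits the epoch into overlapping Hamming-windowed segments, averages the
#' one-sided modified periodograms. Normalized by the window power
#' (`fs * sum(w^2)`) so the integrated PSD approximates the signal variance.
#'
#' @param x numeric vector, one epoch of one region.
#' @param sampling_rate sampling frequency in Hz.
#' @param segment_length segment length in samples (default 2048; ~0.61 Hz
#'   resolution at 1250 Hz).
#' @param overlap_fraction fractional overlap between segments in `[0, 1)`.
#' @return A spectrum: list with `frequencies` (Hz) and `power` (linear,
#'   one-sided), class `"gliodev_spectrum"`.
#' @export
welch_psd <- function(x, sampling_rate, segment_length = 2048L,
                      overlap_fraction = 0.5) {
  if (segment_length > length(x)) {
    stop_arg("segment_length (%d) exceeds epoch length (%d)",
             segment_length, length(x))
  }
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop_arg("overlap_fraction must lie in [0, 1)")
  }
  p <- welch_psd_matrix(matrix(x, nrow = 1L), sampling_rate,
                        segment_length, overlap_fraction)
  structure(list(frequencies = attr(p, "frequencies"), power = p[1L, ]),
            class = "gliodev_spectrum")
}

# Vectorized Welch over rows (regions) of a regions x samples epoch matrix.
# Returns regions x n_freq power matrix with a "frequencies" attribute.
welch_psd_matrix <- function(mat, sampling_rate, segment_length = 2048L,
                             overlap_fraction = 0.5) {
  L <- as.integer(segment_length)
  N <- ncol(mat)
  step <- max(1L, as.integer(round(L * (1 - overlap_fraction))))
  starts <- seq.int(1L, N - L + 1L, by = step)
  w <- hamming_window(L)
  nf <- L %/% 2 + 1L
  scale <- 1 / (sampling_rate * sum(w^2))
  one_sided <- rep(2, nf)
  one_sided[1L] <- 1
  if (L %% 2L == 0L) one_sided[nf] <- 1

  acc <- matrix(0, nrow(mat), nf)
  for (s0 in starts) {
    seg <- t(mat[, s0:(s0 + L - 1L), drop = FALSE]) * w   # samples x regions
    X <- mvfft(seg)[seq_len(nf), , drop = FALSE]
    acc <- acc + t(Mod(X)^2)
  }
  p <- acc / length(starts) * scale
  p <- sweep(p, 2L, one_sided, `*`)
  attr(p, "frequencies") <- (0:(nf - 1L)) * sampling_rate / L
  p
}

#' Average spectra over epochs
#'
#' Element-wise arithmetic mean of linear power across spectra sharing one
#' frequency grid.
#'
#' @param spectra list of spectra from [welch_psd()].
#' @return A spectrum (class `"gliodev_spectrum"`).
#' @export
average_spectra <- function(spectra) {
  stopifnot(length(spectra) >= 1L)
  f <- spectra[[1L]]$frequencies
  for (sp in spectra) {
    if (length(sp$frequencies) != length(f) || any(sp$frequencies != f)) {
      stop_arg("spectra must share an identical frequency grid")
    }
  }
  pw <- rowMeans(vapply(spectra, function(sp) sp$power, numeric(length(f))))
  structure(list(frequencies = f, power = pw), class = "gliodev_spectrum")
}

# log10 model prediction
aperiodic_curve <- function(f, b, k, x) b - log10(k + f^x)

#' Fit the aperiodic model to a power spectrum
#'
#' Fits `L(F) = b - log10(k + F^x)` to the log10 power spectrum over
#' `fit_range` in two passes: an initial fit, then exclusion of points whose
#' positive residual (candidate oscillatory peaks) exceeds one SD of the
#' 2.5%-trimmed residuals, and a refit on the remaining points. In
#' `mode = "fixed"` the knee is pinned at 0 and the model is linear in
#' log10(F); `mode = "knee"` estimates k by nonlinear least squares with
#' multiple restarts.
#'
#' @param spectrum spectrum from [welch_psd()]/[average_spectra()].
#' @param mode `"fixed"` (k = 0, default) or `"knee"`.
#' @param fit_range numeric length 2, fit range in Hz (default 0.5-45,
#'   the broadband filter range).
#' @param peak_threshold_sd residual threshold, in trimmed-residual SDs, for
#'   flagging points as oscillatory peaks.
#' @return List with `offset` (b), `knee` (k), `exponent` (x), `mode`,
#'   `fit_range`, `r_squared` (of the final fit on unflagged points),
#'   `flagged` (logical per fitted bin), `converged`.
#' @export
fit_aperiodic <- function(spectrum, mode = c("fixed", "knee"),
                          fit_range = c(0.5, 45), peak_threshold_sd = 1) {
  mode <- match.arg(mode)
  sel <- spectrum$frequencies >= fit_range[1] & spectrum$frequencies <= fit_range[2]
  f <- spectrum$frequencies[sel]
  p <- spectrum$power[sel]
  if (length(f) < 4L) stop_arg("fewer than 4 frequency bins in fit_range")
  if (any(p <= 0)) stop_arg("power must be positive on the fit range")
  y <- log10(p)

  fit_once <- function(f, y) {
    if (mode == "fixed") {
      lf <- log10(f)
      co <- lm.fit(cbind(1, lf), y)$coefficients
      b <- co[1L]; x <- -co[2L]
      if (x < 0) { x <- 0; b <- mean(y) }   # enforce non-increasing aperiodic curve
      list(b = unname(b), k = 0, x = unname(x), converged = TRUE)
    } else {
      fit_knee(f, y)
    }
  }

  first <- fit_once(f, y)
  r1 <- y - aperiodic_curve(f, first$b, first$k, first$x)
  qs <- quantile(r1, c(0.025, 0.975), names = FALSE)
  trimmed <- r1[r1 >= qs[1] & r1 <= qs[2]]
  s <- sd(if (length(trimmed) >= 3L) trimmed else r1)
  flagged <- if (is.finite(s) && s > 0) r1 > peak_threshold_sd * s else rep(FALSE, length(r1))
  if (sum(!flagged) < max(4L, length(f) %/% 4L)) flagged <- rep(FALSE, length(r1))

  final <- if (any(flagged)) fit_once(f[!flagged], y[!flagged]) else first
  yh <- aperiodic_curve(f[!flagged], final$b, final$k, final$x)
  yy <- y[!flagged]
  ss_tot <- sum((yy - mean(yy))^2)
  r2 <- if (ss_tot > 0) 1 - sum((yy - yh)^2) / ss_tot else 1

  list(offset = final$b, knee = final$k, exponent = final$x, mode = mode,
       fit_range = fit_range, r_squared = r2, flagged = flagged,
       converged = final$converged)
}

# Knee-mode fit: nls (port, bounded) over restarts, Nelder-Mead fallback.
fit_knee <- function(f, y) {
  lf <- log10(f)
  co <- lm.fit(cbind(1, lf), y)$coefficients
  b0 <- unname(co[1L]); x0 <- max(0.1, -unname(co[2L]))
  k_starts <- c(0.01, 1, stats::median(f)^x0, 10)
  best <- NULL
  for (k0 in k_starts) {
    fit <- tryCatch({
      m <- nls(y ~ b - log10(k + f^x),
               start = list(b = b0, k = k0, x = x0),
               lower = c(b = -Inf, k = 0, x = 0), algorithm = "port",
               control = nls.control(maxiter = 200, warnOnly = TRUE))
      list(b = coef(m)[["b"]], k = coef(m)[["k"]], x = coef(m)[["x"]],
           sse = sum(resid(m)^2), converged = m$convInfo$isConv)
    }, error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$sse < best$sse)) best <- fit
  }
  if (is.null(best)) {
    obj <- function(par) {
      sum((y - aperiodic_curve(f, par[1L], exp(par[2L]), exp(par[3L])))^2)
    }
    o <- optim(c(b0, log(1), log(x0)), obj, method = "Nelder-Mead",
               control = list(maxit = 2000))
    best <- list(b = o$par[1L], k = exp(o$par[2L]), x = exp(o$par[3L]),
                 sse = o$value, converged = o$convergence == 0L)
  }
  list(b = best$b, k = best$k, x = best$x, converged = isTRUE(best$converged))
}

#' Epoch-averaged spectra and aperiodic fits for one subject
#'
#' Convenience wrapper: Welch PSD per region and epoch, arithmetic average
#' over epochs, aperiodic fit per region.
#'
#' @param signal epoched-signal object from [simulate_subject()].
#' @param segment_length,overlap_fraction Welch settings.
#' @param mode,fit_range aperiodic fit settings (see [fit_aperiodic()]).
#' @return data.frame(`region_id`, `offset`, `knee`, `exponent`,
#'   `r_squared`, `converged`).
#' @export
subject_offsets <- function(signal, segment_length = 2048L,
                            overlap_fraction = 0.5, mode = "fixed",
                            fit_range = c(0.5, 45)) {
  d <- signal$data
  n <- dim(d)[1L]; n_epochs <- dim(d)[2L]
  acc <- NULL
  for (e in seq_len(n_epochs)) {
    m <- d[, e, , drop = FALSE]
    dim(m) <- c(n, dim(d)[3L])
    p <- welch_psd_matrix(m, signal$sampling_rate,
                          segment_length, overlap_fraction)
    acc <- if (is.null(acc)) p else acc + p
  }
  freqs <- attr(acc, "frequencies")
  pw <- acc / n_epochs
  out <- vector("list", n)
  for (r in seq_len(n)) {
    sp <- structure(list(frequencies = freqs, power = pw[r, ]),
                    class = "gliodev_spectrum")
    ft <- fit_aperiodic(sp, mode = mode, fit_range = fit_range)
    out[[r]] <- data.frame(region_id = r - 1L, offset = ft$offset,
                           knee = ft$knee, exponent = ft$exponent,
                           r_squared = ft$r_squared, converged = ft$converged)
  }
  do.call(rbind, out)
}
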