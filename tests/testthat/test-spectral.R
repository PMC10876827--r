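# Welch spectral estimation and aperiodic (offset/knee/exponent) fitting.

test_that("Welch PSD localizes a pure tone and conserves noise power", {
  fs <- 1250
  t <- (0:4095) / fs
  tone <- sin(2 * pi * 10 * t)
  sp <- welch_psd(tone, fs, segment_length = 2048)
  expect_equal(sp$frequencies[which.max(sp$power)], 10, tolerance = 0.62)

  # Parseval: integrated PSD approximates the variance (white noise)
  set.seed(42)
  fs2 <- 256
  sigma2 <- 2.3
  ratio <- replicate(50, {
    x <- rnorm(1024, sd = sqrt(sigma2))
    sp <- welch_psd(x, fs2, segment_length = 256)
    sum(sp$power) * (fs2 / 256) / sigma2
  })
  expect_lt(abs(mean(ratio) - 1), 0.1)
})

test_that("single full-length segment reproduces the direct windowed periodogram", {
  set.seed(7)
  x <- rnorm(512)
  fs <- 100
  sp <- welch_psd(x, fs, segment_length = 512, overlap_fraction = 0)
  oracle <- periodogram_oracle(x, fs)
  expect_equal(sp$frequencies, oracle$frequencies)
  expect_equal(sp$power, oracle$power, tolerance = 1e-12)

  expect_error(welch_psd(x, fs, segment_length = 1024), "exceeds epoch length")
  expect_error(welch_psd(x, fs, segment_length = 256, overlap_fraction = 1),
               "overlap_fraction")
})

test_that("spectrum averaging is an order-invariant element-wise mean", {
  f <- seq(1, 40, by = 1)
  mk <- function(p) structure(list(frequencies = f, power = p),
                              class = "gliodev_spectrum")
  p <- runif(40, 1, 2)
  expect_equal(average_spectra(list(mk(p), mk(p)))$power, p)
  expect_equal(average_spectra(list(mk(p), mk(3 * p)))$power, 2 * p)
  set.seed(1)
  ps <- lapply(1:5, function(i) mk(runif(40)))
  expect_equal(average_spectra(ps)$power, average_spectra(rev(ps))$power)
  bad <- structure(list(frequencies = f + 0.5, power = p),
                   class = "gliodev_spectrum")
  expect_error(average_spectra(list(mk(p), bad)), "frequency grid")
})

test_that("aperiodic fit recovers noiseless spectra exactly and resists peaks", {
  f <- seq(0.5, 45, by = 0.5)
  noiseless <- structure(list(frequencies = f, power = 10^(1.5 - 2 * log10(f))),
                         class = "gliodev_spectrum")
  ft <- fit_aperiodic(noiseless)
  expect_equal(ft$offset, 1.5, tolerance = 1e-6)
  expect_equal(ft$exponent, 2, tolerance = 1e-6)
  expect_equal(ft$knee, 0)

  # one Gaussian log-power bump at 10 Hz, height 0.5
  y <- 1.5 - 2 * log10(f) + 0.5 * exp(-(f - 10)^2 / (2 * 1.5^2))
  bumped <- structure(list(frequencies = f, power = 10^y),
                      class = "gliodev_spectrum")
  ftb <- fit_aperiodic(bumped)
  expect_lt(abs(ftb$offset - 1.5), 0.05)

  # grid-search oracle over (b, x): least-trimmed-squares on the same data
  grid_b <- seq(1.3, 1.7, by = 0.005)
  grid_x <- seq(1.8, 2.2, by = 0.005)
  best <- c(Inf, NA, NA)
  for (b in grid_b) for (x in grid_x) {
    r2 <- sort((y - (b - x * log10(f)))^2)
    sse <- sum(r2[seq_len(floor(0.8 * length(r2)))])
    if (sse < best[1]) best <- c(sse, b, x)
  }
  expect_lt(abs(best[2] - 1.5), 0.05)          # oracle agrees the offset is ~1.5
  expect_lt(abs(ftb$offset - best[2]), 0.05)   # fit agrees with the oracle
})

test_that("knee-mode fit recovers the knee within 10%", {
  f <- seq(0.5, 45, by = 0.5)
  sp <- structure(list(frequencies = f, power = 10^(1 - log10(5 + f^2))),
                  class = "gliodev_spectrum")
  ft <- fit_aperiodic(sp, mode = "knee")
  expect_lt(abs(ft$knee - 5) / 5, 0.10)
  expect_equal(ft$offset, 1, tolerance = 0.05)
})

test_that("offset is scaling-equivariant and exponent is monotone in truth", {
  sig <- tiny_signal(n_per_hemisphere = 2, n_epochs = 3, seed = 2)
  sp <- average_spectra(lapply(1:3, function(e) {
    welch_psd(sig$data[1, e, ], sig$sampling_rate)
  }))
  ft0 <- fit_aperiodic(sp)
  sp_scaled <- structure(list(frequencies = sp$frequencies,
                              power = sp$power * 10^1.7),
                         class = "gliodev_spectrum")
  ft1 <- fit_aperiodic(sp_scaled)
  expect_equal(ft1$offset - ft0$offset, 1.7, tolerance = 1e-9)
  expect_equal(ft1$exponent, ft0$exponent, tolerance = 1e-12)

  f <- seq(0.5, 45, by = 0.5)
  rec <- sapply(c(0.5, 1, 2, 3), function(x_true) {
    sp <- structure(list(frequencies = f, power = 10^(1 - x_true * log10(f))),
                    class = "gliodev_spectrum")
    fit_aperiodic(sp)$exponent
  })
  expect_true(all(diff(rec) > 0))
})

test_that("offset estimates tighten as epochs accumulate", {
  sd_at <- function(n_epochs) {
    ests <- sapply(1:8, function(seed) {
      sig <- tiny_signal(n_per_hemisphere = 2, n_epochs = n_epochs,
                         seed = 100 + seed, epoch_length = 2048)
      sp <- average_spectra(lapply(seq_len(n_epochs), function(e) {
        welch_psd(sig$data[1, e, ], sig$sampling_rate, segment_length = 1024)
      }))
      fit_aperiodic(sp)$offset
    })
    sd(ests)
  }
  expect_gt(sd_at(2), sd_at(12))
})
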