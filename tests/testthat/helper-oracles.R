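# Independent oracles used to cross-check package implementations.

# Local clustering coefficient by explicit triple enumeration, O(n^3).
cc_bruteforce <- function(A) {
  n <- nrow(A)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    tri <- 0L
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      if (A[nb[a], nb[b]] == 1) tri <- tri + 1L
    }
    out[i] <- 2 * tri / (k * (k - 1))
  }
  out
}

# Principal eigenvector by full symmetric eigendecomposition.
ec_eigen_oracle <- function(A) {
  e <- eigen(A, symmetric = TRUE)
  v <- e$vectors[, which.max(e$values)]
  v <- v * sign(v[which.max(abs(v))])
  v / sqrt(sum(v^2))
}

# PLI by the literal per-sample definition.
pli_bruteforce <- function(phi_i, phi_j) {
  s <- sign(sin(phi_i - phi_j))
  abs(mean(s))
}

# Single Hamming-windowed one-sided periodogram (Welch with one segment).
periodogram_oracle <- function(x, fs) {
  L <- length(x)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  X <- fft(x * w)[1:(L %/% 2 + 1)]
  p <- Mod(X)^2 / (fs * sum(w^2))
  sc <- rep(2, L %/% 2 + 1)
  sc[1] <- 1
  if (L %% 2 == 0) sc[L %/% 2 + 1] <- 1
  list(frequencies = (0:(L %/% 2)) * fs / L, power = p * sc)
}

# Benjamini-Hochberg step-up by the textbook formula.
bh_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# Exact two-sided Mann-Whitney p by enumerating all group labelings.
mwu_exact_enum <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  idx <- utils::combn(length(pooled), n_a)
  u_of <- function(sel) {
    aa <- pooled[sel]
    bb <- pooled[-sel]
    sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
  }
  u_obs <- u_of(seq_len(n_a))
  us <- apply(idx, 2, u_of)
  mu <- n_a * length(b) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Random symmetric binary adjacency (no self loops); optionally forced connected.
random_adjacency <- function(n, p_edge, connected = FALSE) {
  repeat {
    A <- matrix(0L, n, n)
    ut <- which(upper.tri(A))
    A[ut] <- rbinom(length(ut), 1L, p_edge)
    A <- A + t(A)
    if (!connected) return(A)
    # BFS connectivity check
    seen <- logical(n)
    queue <- 1L
    seen[1L] <- TRUE
    while (length(queue) > 0) {
      v <- queue[1L]
      queue <- queue[-1L]
      nb <- which(A[v, ] == 1 & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    if (all(seen)) return(A)
  }
}

# Tiny epoched-signal fixture: 2*n_per_hemisphere regions, aperiodic noise
# plus optional oscillators.
tiny_signal <- function(n_per_hemisphere = 2, n_epochs = 4, seed = 1,
                        offset = 1.5, exponent = 2, oscillators = list(),
                        epoch_length = 4096, sampling_rate = 1250) {
  atlas <- make_atlas(n_per_hemisphere, seed = seed)
  gt <- list(offset = rep(offset, nrow(atlas)),
             exponent = rep(exponent, nrow(atlas)),
             knee = 0, oscillators = oscillators)
  entry <- list(subject_id = "s1", group = "HC", n_epochs = n_epochs,
                sampling_rate = sampling_rate, epoch_length = epoch_length)
  simulate_subject(atlas, entry, gt, seed = seed)
}
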