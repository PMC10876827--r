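# Graph-metrics module: proportional thresholding/binarization and the two
# regional metrics used downstream — local clustering coefficient (CC,
# segregation) and eigenvector centrality (EC, integration).

#' Proportional threshold and binarize a connectivity matrix
#'
#' Keeps the `round(density * M)` strongest upper-triangle weights
#' (`M = n(n-1)/2`) as edges, halves rounded away from zero. Ties at the
#' cutoff are broken deterministically by ascending `(i, j)` lexicographic
#' order, which also makes the 20% edge set a subset of the 30% edge set.
#'
#' @param conn connectivity object from [pli_matrix()] or a symmetric
#'   numeric matrix.
#' @param density target edge density in (0, 1); the pipeline uses 0.20 and
#'   0.30.
#' @return Binary network: list with `adjacency` (n x n 0/1 matrix),
#'   `density`, `edge_count`.
#' @export
proportional_threshold <- function(conn, density) {
  W <- if (inherits(conn, "gliodev_connectivity")) conn$values else conn
  if (density <= 0 || density >= 1) stop_arg("density must lie in (0, 1)")
  n <- nrow(W)
  if (n != ncol(W) || any(abs(W - t(W)) > 1e-12)) {
    stop_arg("connectivity matrix must be square and symmetric")
  }
  M <- n * (n - 1L) / 2
  m_edges <- as.integer(round_half_away(density * M))
  ut <- which(upper.tri(W), arr.ind = TRUE)
  o <- order(-W[ut], ut[, 1L], ut[, 2L])    # strongest first, lexicographic ties
  pick <- ut[o[seq_len(m_edges)], , drop = FALSE]
  A <- matrix(0L, n, n)
  A[pick] <- 1L
  A <- A + t(A)
  list(adjacency = A, density = density, edge_count = m_edges)
}

as_adjacency <- function(network) {
  A <- if (is.list(network)) network$adjacency else network
  if (!all(A %in% c(0, 1)) || any(diag(A) != 0) || any(A != t(A))) {
    stop_arg("adjacency must be binary, symmetric, with zero diagonal")
  }
  A
}

#' Local clustering coefficient
#'
#' `CC_i = 2 T_i / (k_i (k_i - 1))` with `T_i` the triangles through node i
#' and `k_i` its degree; nodes with degree < 2 get 0.
#'
#' @param network binary network from [proportional_threshold()] or a binary
#'   symmetric adjacency matrix.
#' @return Numeric vector of per-region CC values in `[0, 1]`.
#' @export
clustering_coefficient <- function(network) {
  A <- as_adjacency(network)
  k <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2
  ifelse(k < 2, 0, 2 * tri / (k * (k - 1)))
}

#' Eigenvector centrality
#'
#' Non-negative principal eigenvector of the adjacency matrix by power
#' iteration from the uniform vector, normalized to unit Euclidean norm.
#' Iteration runs on `A + I` (same eigenvectors, spectrum shifted positive)
#' so that bipartite components — where plain power iteration oscillates —
#' still converge to the principal eigenvector of `A`. Convergence is
#' declared when successive iterates differ by less than `tol` in max-norm.
#'
#' @param network binary network or adjacency matrix with at least one edge.
#' @param tol convergence tolerance (max-norm).
#' @param max_iter maximum number of iterations.
#' @return Numeric vector of per-region EC values (unit Euclidean norm).
#' @export
eigenvector_centrality <- function(network, tol = 1e-12, max_iter = 10000L) {
  A <- as_adjacency(network)
  if (sum(A) == 0) stop_arg("eigenvector centrality undefined: network has no edges")
  n <- nrow(A)
  v <- rep(1 / sqrt(n), n)
  for (it in seq_len(max_iter)) {
    v_new <- A %*% v + v                 # (A + I) v
    nrm <- sqrt(sum(v_new^2))
    if (nrm == 0) stop_arg("power iteration collapsed to the zero vector")
    v_new <- as.numeric(v_new) / nrm
    if (max(abs(v_new - v)) < tol) return(v_new)
    v <- v_new
  }
  stop_arg("eigenvector centrality did not converge in %d iterations (last delta %.3g)",
           max_iter, max(abs(v_new - v)))
}

#' Regional graph metrics across bands and densities for one subject
#'
#' @param connectivities named list (by band) of connectivity objects.
#' @param densities numeric vector of target densities (default 0.20, 0.30).
#' @return Long data.frame(`band`, `density`, `region_id`, `cc`, `ec`).
#' @export
subject_graph_metrics <- function(connectivities, densities = c(0.20, 0.30)) {
  out <- list()
  for (band_name in names(connectivities)) {
    conn <- connectivities[[band_name]]
    for (dens in densities) {
      net <- proportional_threshold(conn, dens)
      cc <- clustering_coefficient(net)
      ec <- eigenvector_centrality(net)
      out[[length(out) + 1L]] <- data.frame(
        band = band_name, density = dens,
        region_id = 0:(nrow(net$adjacency) - 1L),
        cc = cc, ec = ec, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
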