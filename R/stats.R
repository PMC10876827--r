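# Statistics module: rank-based group comparisons, spatially constrained
# spin permutation tests, within-subject linear mixed models, per-subject
# correlations and Benjamini-Hochberg FDR correction.

#' Mann-Whitney U test
#'
#' Two-sided test; the reported statistic is U for `sample_a` (pairs where a
#' exceeds b, ties counted one half). The p-value is exact (full enumeration)
#' when both samples have at most 20 observations and no ties are present,
#' otherwise a tie-corrected normal approximation is used.
#'
#' @param sample_a,sample_b numeric vectors, both nonempty.
#' @return List with `test`, `statistic` (U), `p`, `n` (group sizes).
#' @export
mann_whitney_u <- function(sample_a, sample_b) {
  a <- sample_a[!is.na(sample_a)]
  b <- sample_b[!is.na(sample_b)]
  if (length(a) == 0L || length(b) == 0L) {
    stop_arg("both samples must be nonempty")
  }
  ranks <- rank(c(a, b))
  u_a <- sum(ranks[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  ties <- any(duplicated(c(a, b)))
  exact <- !ties && length(a) <= 20L && length(b) <= 20L
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = FALSE))
  list(test = "mann_whitney_u", statistic = unname(u_a), p = ht$p.value,
       n = c(length(a), length(b)))
}

#' Wilcoxon signed-rank test
#'
#' Two-sided paired test; zero differences are dropped; the reported W is the
#' smaller of the positive- and negative-rank sums (tied absolute differences
#' get averaged ranks).
#'
#' @param paired_a,paired_b numeric vectors of equal length.
#' @return List with `test`, `statistic` (W), `p`, `n` (nonzero pairs).
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b) {
  if (length(paired_a) != length(paired_b)) {
    stop_arg("paired samples must have equal length")
  }
  d <- paired_a - paired_b
  d <- d[!is.na(d) & d != 0]
  if (length(d) == 0L) stop_arg("all paired differences are zero")
  r <- rank(abs(d))
  v_pos <- sum(r[d > 0])
  w <- min(v_pos, sum(r) - v_pos)
  exact <- !any(duplicated(abs(d))) && length(d) <= 25L
  ht <- suppressWarnings(stats::wilcox.test(d, exact = exact, correct = FALSE))
  list(test = "wilcoxon_signed_rank", statistic = unname(w), p = ht$p.value,
       n = length(d))
}

# Haar-random rotation in SO(3) via QR of a Gaussian matrix.
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9L), 3L, 3L))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

# Greedy bijective assignment: closest rotated/original pairs first.
greedy_assignment <- function(sim) {
  n <- nrow(sim)
  o <- order(-sim)
  rows <- ((o - 1L) %% n) + 1L
  cols <- ((o - 1L) %/% n) + 1L
  perm <- integer(n)
  used_r <- logical(n); used_c <- logical(n)
  filled <- 0L
  for (idx in seq_along(o)) {
    i <- rows[idx]; j <- cols[idx]
    if (used_r[i] || used_c[j]) next
    perm[i] <- j
    used_r[i] <- TRUE; used_c[j] <- TRUE
    filled <- filled + 1L
    if (filled == n) break
  }
  perm
}

#' Spatially constrained spin permutation test
#'
#' Pearson correlation of two regional maps against a null that preserves
#' spatial autocorrelation: each permutation draws one random 3D rotation,
#' applies it to the left-hemisphere centroids and its sagittal mirror to the
#' right hemisphere, reassigns every rotated centroid to the nearest original
#' centroid within its hemisphere (`method = "nearest"`, duplicates allowed;
#' `"bijective"` uses a distance-greedy one-to-one matching), permutes
#' `map_a` accordingly and recomputes the correlation. The two-sided p-value
#' is `(1 + #{|r_null| >= |r_obs|}) / (1 + n_perm)`.
#'
#' @param map_a,map_b numeric regional maps, one value per atlas region
#'   (ordered by `region_id`).
#' @param atlas atlas data.frame with unit-norm centroids.
#' @param n_perm number of permutations (default 5000).
#' @param seed integer seed.
#' @param method `"nearest"` (default) or `"bijective"`.
#' @return List with `r`, `p_spin`, `n_perm`, `seed`, `method`.
#' @export
spin_test <- function(map_a, map_b, atlas, n_perm = 5000L, seed = 1L,
                      method = c("nearest", "bijective")) {
  method <- match.arg(method)
  validate_atlas(atlas)
  n <- nrow(atlas)
  if (length(map_a) != n || length(map_b) != n) {
    stop_arg("maps must have one value per atlas region")
  }
  cen <- atlas_centroids(atlas)
  if (any(abs(sqrt(rowSums(cen^2)) - 1) > 1e-6)) {
    stop_arg("atlas centroids must lie on the unit sphere")
  }
  ord <- order(atlas$region_id)
  hemi <- atlas$hemisphere[ord]
  left <- which(hemi == "left")
  right <- which(hemi == "right")
  Cl <- cen[left, , drop = FALSE]
  Cr <- cen[right, , drop = FALSE]
  M <- diag(c(-1, 1, 1))

  r_obs <- cor(map_a, map_b)
  r_null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      R <- random_rotation()
      Rm <- M %*% R %*% M
      sim_l <- (Cl %*% t(R)) %*% t(Cl)   # rotated-left vs original-left
      sim_r <- (Cr %*% t(Rm)) %*% t(Cr)
      perm <- integer(n)
      if (method == "nearest") {
        perm[left] <- left[max.col(sim_l, ties.method = "first")]
        perm[right] <- right[max.col(sim_r, ties.method = "first")]
      } else {
        perm[left] <- left[greedy_assignment(sim_l)]
        perm[right] <- right[greedy_assignment(sim_r)]
      }
      cor(map_a[perm], map_b)
    }, numeric(1L))
  })
  p <- (1 + sum(abs(r_null) >= abs(r_obs))) / (1 + n_perm)
  list(r = r_obs, p_spin = p, n_perm = as.integer(n_perm), seed = seed,
       method = method)
}

#' Linear mixed model of offset deviation on network deviations
#'
#' Fits `offset_dev ~ 1 + EC_dev + CC_dev` (or the given columns) with a
#' random intercept per subject, by REML (`lme4`). Inference is Wald: z =
#' estimate / SE, two-sided normal p, 95% CI. Standardized coefficients come
#' from a refit on variables z-scored across all included observations.
#' Singular fits are flagged, not masked.
#'
#' @param data long data.frame, one row per subject x region.
#' @param response response column (default `"offset_dev"`).
#' @param predictors predictor columns (default `c("EC_dev", "CC_dev")`).
#' @param subject grouping column (default `"subject_id"`).
#' @return List with `coefficients` (data.frame: term, estimate, ci_lo,
#'   ci_hi, std_beta, z, p), `ranef_var`, `residual_var`, `n_subjects`,
#'   `n_obs`, `singular`.
#' @export
fit_lmm <- function(data, response = "offset_dev",
                    predictors = c("EC_dev", "CC_dev"),
                    subject = "subject_id") {
  cols <- c(response, predictors, subject)
  if (!all(cols %in% names(data))) {
    stop_arg("data is missing columns: %s",
             paste(setdiff(cols, names(data)), collapse = ", "))
  }
  data <- data[stats::complete.cases(data[, cols]), cols]
  if (length(unique(data[[subject]])) < 2L) {
    stop_arg("at least 2 subjects are required")
  }
  fml <- stats::as.formula(sprintf("%s ~ 1 + %s + (1 | %s)", response,
                                   paste(predictors, collapse = " + "), subject))
  # optimizer chatter (near-singular or noiseless fits) is expected on
  # degenerate inputs; singularity is reported via the `singular` flag instead
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(fml, data = data, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  ci <- cbind(est - qnorm(0.975) * se, est + qnorm(0.975) * se)

  zdata <- data
  for (v in c(response, predictors)) zdata[[v]] <- as.numeric(scale(zdata[[v]]))
  zfit <- suppressMessages(suppressWarnings(
    lme4::lmer(fml, data = zdata, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  std_beta <- lme4::fixef(zfit)

  vc <- as.data.frame(lme4::VarCorr(fit))
  list(
    coefficients = data.frame(
      term = names(est), estimate = unname(est),
      ci_lo = ci[, 1L], ci_hi = ci[, 2L],
      std_beta = unname(std_beta[names(est)]),
      z = unname(z), p = unname(p),
      row.names = NULL, stringsAsFactors = FALSE),
    ranef_var = vc$vcov[vc$grp == subject][1L],
    residual_var = vc$vcov[vc$grp == "Residual"][1L],
    n_subjects = length(unique(data[[subject]])),
    n_obs = nrow(data),
    singular = lme4::isSingular(fit))
}

#' Per-subject Pearson correlations between two regional deviation maps
#'
#' @param data long data.frame with subject, x and y columns.
#' @param x_col,y_col value columns to correlate within each subject.
#' @param subject grouping column.
#' @return data.frame(`subject_id`, `r`, `n_regions`); `r` is `NA` when a
#'   map is constant within the subject.
#' @export
per_subject_correlation <- function(data, x_col, y_col,
                                    subject = "subject_id") {
  ids <- unique(data[[subject]])
  out <- lapply(ids, function(sid) {
    rows <- data[data[[subject]] == sid, ]
    ok <- !is.na(rows[[x_col]]) & !is.na(rows[[y_col]])
    rows <- rows[ok, ]
    if (nrow(rows) < 3L) stop_arg("subject '%s' has fewer than 3 regions", sid)
    x <- rows[[x_col]]; y <- rows[[y_col]]
    r <- if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
    data.frame(subject_id = sid, r = r, n_regions = nrow(rows),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with monotonicity enforcement. The pipeline's
#' default family is the 6 tests of one measure/contrast across 3 frequency
#' bands x 2 network densities.
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
fdr_bh <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    stop_arg("p-values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}
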