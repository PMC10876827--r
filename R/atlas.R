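#' Build a synthetic mirrored cortical atlas
#'
#' Places `n_per_hemisphere` region centroids quasi-uniformly on the left half
#' (`x < 0`) of the unit sphere with a Fibonacci lattice, then mirrors them
#' through the sagittal plane (`x = 0`) to form the right hemisphere. Each
#' region is paired with its mirror image (its contralateral homologue), so
#' the homologue mapping is a hemisphere-crossing involution. The seed only
#' rotates/jitters the lattice angles; centroid `x` coordinates come from the
#' lattice and are strictly negative on the left.
#'
#' @param n_per_hemisphere number of regions per hemisphere (>= 2); the
#'   default 105 yields the 210-region layout used throughout the pipeline.
#' @param seed integer seed for the angular jitter.
#' @param jitter standard deviation (radians) of the azimuthal jitter.
#' @return A data.frame with columns `region_id` (0-based integer),
#'   `hemisphere` (`"left"`/`"right"`), `homologue_id`, and unit-norm
#'   centroid coordinates `x`, `y`, `z`.
#' @examples
#' atlas <- make_atlas(4, seed = 1)
#' all(atlas$homologue_id[atlas$homologue_id + 1L] == atlas$region_id)
#' @export
make_atlas <- function(n_per_hemisphere = 105L, seed = 1L, jitter = 0.05) {
  if (!is.numeric(n_per_hemisphere) || length(n_per_hemisphere) != 1L ||
      n_per_hemisphere < 2 || n_per_hemisphere != round(n_per_hemisphere)) {
    stop_arg("n_per_hemisphere must be an integer >= 2, got %s",
             deparse(n_per_hemisphere))
  }
  nh <- as.integer(n_per_hemisphere)
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(nh) - 1L
  xs <- -((i + 0.5) / nh)               # uniform in (-1, 0): uniform area on hemisphere
  theta <- with_seed(seed, {
    i * golden + runif(1L, 0, 2 * pi) + rnorm(nh, 0, jitter)
  })
  r <- sqrt(pmax(0, 1 - xs^2))
  left <- cbind(x = xs, y = r * cos(theta), z = r * sin(theta))
  right <- left
  right[, "x"] <- -right[, "x"]

  data.frame(
    region_id = 0:(2L * nh - 1L),
    hemisphere = rep(c("left", "right"), each = nh),
    homologue_id = c(nh + i, i),
    x = c(left[, "x"], right[, "x"]),
    y = c(left[, "y"], right[, "y"]),
    z = c(left[, "z"], right[, "z"]),
    stringsAsFactors = FALSE
  )
}

# centroid matrix (n x 3), rows ordered by region_id
atlas_centroids <- function(atlas) {
  as.matrix(atlas[order(atlas$region_id), c("x", "y", "z")])
}

validate_atlas <- function(atlas) {
  need <- c("region_id", "hemisphere", "homologue_id", "x", "y", "z")
  if (!all(need %in% names(atlas))) {
    stop_arg("atlas is missing columns: %s",
             paste(setdiff(need, names(atlas)), collapse = ", "))
  }
  n <- nrow(atlas)
  if (n %% 2L != 0L) stop_arg("atlas must have an even number of regions")
  if (!setequal(atlas$region_id, 0:(n - 1L))) {
    stop_arg("atlas region_id must be the integers 0..n-1")
  }
  hom <- atlas$homologue_id[match(0:(n - 1L), atlas$region_id)]
  if (!all(hom[hom + 1L] == 0:(n - 1L))) {
    stop_arg("homologue pairing must be an involution")
  }
  invisible(atlas)
}
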