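# Deviation module: standardize regional metrics against the healthy-control
# cohort ("dev" values) and partition each patient's regions into
# (peri)tumoral, contralateral-homologue, rest-of-brain and excluded areas.

#' Standardize regional values against the healthy-control cohort
#'
#' Replaces every subject's regional value by its z-score relative to the
#' healthy controls' regional mean and sample standard deviation (denominator
#' n - 1). By construction the HC cohort standardized against itself has
#' per-region mean 0 and SD 1.
#'
#' @param values long data.frame with columns `subject_id`, `region_id`, and
#'   the value column.
#' @param hc_subject_ids character vector of control subject ids (>= 2).
#' @param value_col name of the value column (default `"value"`).
#' @return The input data.frame with an added `dev` column.
#' @export
standardize_to_hc <- function(values, hc_subject_ids, value_col = "value") {
  if (!all(c("subject_id", "region_id", value_col) %in% names(values))) {
    stop_arg("values must have columns subject_id, region_id, %s", value_col)
  }
  if (length(unique(hc_subject_ids)) < 2L) {
    stop_arg("at least 2 HC subjects are required for standardization")
  }
  hc <- values[values$subject_id %in% hc_subject_ids, ]
  if (nrow(hc) == 0L) stop_arg("no rows match the given HC subject ids")
  mu <- tapply(hc[[value_col]], hc$region_id, mean)
  sdv <- tapply(hc[[value_col]], hc$region_id, sd)
  bad <- names(sdv)[!is.finite(sdv) | sdv == 0]
  if (length(bad) > 0L) {
    stop_arg("zero or undefined HC SD in region(s): %s",
             paste(head(bad, 5L), collapse = ", "))
  }
  key <- as.character(values$region_id)
  if (any(!key %in% names(mu))) {
    stop_arg("some regions have no HC reference values")
  }
  values$dev <- (values[[value_col]] - mu[key]) / sdv[key]
  values
}

#' Assign tumor-referenced area labels to a patient's regions
#'
#' Labels: `peritumoral` for overlap >= 0.12; `excluded` for overlap in
#' (0, 0.12) (neither tumoral nor strictly tumor-free); `homologue` for the
#' mirror images of the peritumoral set; `rest` for tumor-free regions that
#' are not homologues. The patient is flagged `excluded_patient` (for
#' peritumoral/homologue analyses only) when the peritumoral set is empty or
#' spans both hemispheres.
#'
#' @param overlap data.frame(`region_id`, `overlap_fraction`) for one
#'   patient.
#' @param atlas atlas data.frame.
#' @param threshold inclusion threshold on the overlap fraction (default
#'   0.12).
#' @return data.frame(`region_id`, `label`) with attribute
#'   `excluded_patient` (logical).
#' @export
assign_areas <- function(overlap, atlas, threshold = 0.12) {
  validate_atlas(atlas)
  if (any(!overlap$region_id %in% atlas$region_id)) {
    stop_arg("overlap table contains region ids absent from the atlas")
  }
  if (any(overlap$overlap_fraction < 0 | overlap$overlap_fraction > 1)) {
    stop_arg("overlap fractions must lie in [0, 1]")
  }
  n <- nrow(atlas)
  frac <- numeric(n)
  frac[overlap$region_id + 1L] <- overlap$overlap_fraction
  hom <- atlas$homologue_id[match(0:(n - 1L), atlas$region_id)]
  hemi <- atlas$hemisphere[match(0:(n - 1L), atlas$region_id)]

  peri <- frac >= threshold
  sub <- frac > 0 & frac < threshold
  homo <- rep(FALSE, n)
  homo[hom[peri] + 1L] <- TRUE

  label <- rep("rest", n)
  label[homo] <- "homologue"
  label[sub] <- "excluded"
  label[peri] <- "peritumoral"

  excluded_patient <- !any(peri) || length(unique(hemi[peri])) > 1L
  structure(data.frame(region_id = 0:(n - 1L), label = label,
                       stringsAsFactors = FALSE),
            excluded_patient = excluded_patient)
}

#' Per-subject area means of deviation values
#'
#' Patients get the arithmetic mean of `dev` over regions in each area
#' (`peritumoral`, `homologue`, `rest`); controls get a whole-brain mean over
#' all regions. Areas that are empty — or unavailable because the patient is
#' flagged excluded for tumor-referenced analyses — yield `NA`, never 0.
#'
#' @param dev_map long data.frame with `subject_id`, `region_id`, `dev`.
#' @param assignments named list (by patient subject_id) of area assignments
#'   from [assign_areas()].
#' @param cohort subjects data.frame with `subject_id`, `group`.
#' @return data.frame(`subject_id`, `group`, `area`, `mean_dev`, `n_regions`).
#' @export
area_summary <- function(dev_map, assignments, cohort) {
  out <- list()
  for (s in seq_len(nrow(cohort))) {
    sid <- cohort$subject_id[s]
    rows <- dev_map[dev_map$subject_id == sid, ]
    if (nrow(rows) == 0L) stop_arg("no deviation values for subject '%s'", sid)
    if (cohort$group[s] == "HC") {
      out[[length(out) + 1L]] <- data.frame(
        subject_id = sid, group = "HC", area = "whole_brain",
        mean_dev = mean(rows$dev), n_regions = nrow(rows),
        stringsAsFactors = FALSE)
      next
    }
    asg <- assignments[[sid]]
    if (is.null(asg)) stop_arg("no area assignment for patient '%s'", sid)
    excluded <- isTRUE(attr(asg, "excluded_patient"))
    lab <- asg$label[match(rows$region_id, asg$region_id)]
    for (area in c("peritumoral", "homologue", "rest")) {
      vals <- rows$dev[lab == area]
      unavailable <- (area %in% c("peritumoral", "homologue") && excluded) ||
        length(vals) == 0L
      out[[length(out) + 1L]] <- data.frame(
        subject_id = sid, group = "patient", area = area,
        mean_dev = if (unavailable) NA_real_ else mean(vals),
        n_regions = if (unavailable) 0L else length(vals),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
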