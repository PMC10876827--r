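# Pipeline module: orchestrates spectral -> connectivity -> graph metrics ->
# deviations -> statistics for every frequency band and network density, and
# writes tidy result tables plus a run manifest.

#' Pipeline configuration
#'
#' Defaults reproduce the study's printed settings: delta/theta/lower-alpha
#' bands, network densities 20% and 30%, Welch segments of 2048 samples with
#' 50% overlap, fixed-mode (k = 0) aperiodic fits over 0.5-45 Hz, 5000 spin
#' permutations, subject-level area means as unit of observation, and FDR
#' families spanning the 3 bands x 2 densities.
#'
#' @param densities network densities in (0, 1).
#' @param bands band definitions (see [default_bands()]).
#' @param segment_length,overlap_fraction Welch settings.
#' @param fit_mode,fit_range aperiodic fit settings.
#' @param spin_n_perm,spin_method spin-test settings.
#' @param unit_of_observation `"subject_means"` (default) or
#'   `"pooled_regions"` for the area group tests.
#' @param lmm_groups groups for which within-subject mixed models are fitted.
#' @param run_area_tests,run_within_tests,run_spin,run_lmm,run_subject_correlations
#'   analysis toggles.
#' @param seed integer seed for the stochastic stages (spin test).
#' @param out_dir optional output directory for TSV tables and the manifest.
#' @return Named list of settings.
#' @export
pipeline_config <- function(densities = c(0.20, 0.30), bands = default_bands(),
                            segment_length = 2048L, overlap_fraction = 0.5,
                            fit_mode = "fixed", fit_range = c(0.5, 45),
                            spin_n_perm = 5000L, spin_method = "nearest",
                            unit_of_observation = c("subject_means", "pooled_regions"),
                            lmm_groups = c("patient", "HC"),
                            run_area_tests = TRUE, run_within_tests = TRUE,
                            run_spin = TRUE, run_lmm = TRUE,
                            run_subject_correlations = TRUE,
                            seed = 1L, out_dir = NULL) {
  list(densities = densities, bands = bands,
       segment_length = as.integer(segment_length),
       overlap_fraction = overlap_fraction,
       fit_mode = fit_mode, fit_range = fit_range,
       spin_n_perm = as.integer(spin_n_perm), spin_method = spin_method,
       unit_of_observation = match.arg(unit_of_observation),
       lmm_groups = lmm_groups,
       run_area_tests = run_area_tests, run_within_tests = run_within_tests,
       run_spin = run_spin, run_lmm = run_lmm,
       run_subject_correlations = run_subject_correlations,
       seed = seed, out_dir = out_dir)
}

# Per-subject feature extraction: aperiodic offsets and graph metrics.
extract_subject_features <- function(signal, config) {
  offs <- subject_offsets(signal,
                          segment_length = config$segment_length,
                          overlap_fraction = config$overlap_fraction,
                          mode = config$fit_mode, fit_range = config$fit_range)
  conns <- lapply(config$bands, function(b) subject_connectivity(signal, b))
  metrics <- subject_graph_metrics(conns, config$densities)
  list(offsets = offs, metrics = metrics)
}

area_test_block <- function(area_means, metric, band, density) {
  hc <- area_means$mean_dev[area_means$group == "HC" &
                              area_means$area == "whole_brain"]
  out <- list()
  for (area in c("peritumoral", "homologue", "rest")) {
    pat <- area_means$mean_dev[area_means$group == "patient" &
                                 area_means$area == area]
    tst <- mann_whitney_u(pat, hc)
    out[[length(out) + 1L]] <- data.frame(
      metric = metric, band = band, density = density, contrast = area,
      mean_dev = mean(pat, na.rm = TRUE), sd_dev = sd(pat[!is.na(pat)]),
      statistic = tst$statistic, p = tst$p,
      n_patients = tst$n[1L], n_hc = tst$n[2L], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Run the full analysis pipeline on a synthetic or loaded study
#'
#' Executes, for every subject, Welch spectra and aperiodic-offset fits plus
#' band-specific PLI connectivity and graph metrics (streaming: one subject's
#' signal in memory at a time); standardizes all regional values against the
#' healthy controls; assigns tumor-referenced areas; and runs the configured
#' statistics: Mann-Whitney area contrasts against HC whole-brain values,
#' within-patient Wilcoxon tests ((peri)tumoral vs homologue), group-level
#' spin-test correlations of raw regional means, within-subject linear mixed
#' models (`offset_dev ~ EC_dev + CC_dev`, random intercept per subject) and
#' per-subject Pearson correlations. Benjamini-Hochberg FDR is applied per
#' measure/contrast family across bands and densities (for mixed models:
#' across the non-intercept terms of all band/density fits within a group).
#'
#' @param study study bundle from [simulate_study()], or a directory written
#'   by [write_study()].
#' @param config configuration from [pipeline_config()].
#' @return Results bundle (named list of data.frames); written as TSV plus a
#'   `manifest.json` when `config$out_dir` is set.
#' @export
run_pipeline <- function(study, config = pipeline_config()) {
  if (is.character(study)) study <- load_study(study)
  atlas <- validate_atlas(study$atlas)
  cohort <- study$cohort
  n <- nrow(atlas)
  band_names <- names(config$bands)

  offsets <- list(); metrics <- list()
  for (s in seq_len(nrow(cohort))) {
    sid <- cohort$subject_id[s]
    signal <- if (!is.null(study$signal_paths)) {
      read_signal_bin(study$signal_paths[[sid]])
    } else {
      subject_signal(study, sid)
    }
    feats <- extract_subject_features(signal, config)
    offsets[[sid]] <- cbind(subject_id = sid, feats$offsets,
                            stringsAsFactors = FALSE)
    metrics[[sid]] <- cbind(subject_id = sid, feats$metrics,
                            stringsAsFactors = FALSE)
    rm(signal)
  }
  offsets <- do.call(rbind, offsets)
  metrics <- do.call(rbind, metrics)
  analyze_features(offsets, metrics, study, config)
}

#' Run the deviation and statistics stages on precomputed features
#'
#' Takes the per-subject regional features (aperiodic offsets and graph
#' metrics, e.g. cached as TSV by an earlier stage) and performs
#' standardization, area assignment and the configured statistics exactly as
#' [run_pipeline()] would.
#'
#' @param offsets data.frame(`subject_id`, `region_id`, `offset`, ...).
#' @param metrics data.frame(`subject_id`, `band`, `density`, `region_id`,
#'   `cc`, `ec`).
#' @param study study bundle (signals are not touched).
#' @param config configuration from [pipeline_config()].
#' @return Results bundle (named list of data.frames).
#' @export
analyze_features <- function(offsets, metrics, study, config = pipeline_config()) {
  if (is.character(study)) study <- load_study(study)
  atlas <- validate_atlas(study$atlas)
  cohort <- study$cohort
  n <- nrow(atlas)
  band_names <- names(config$bands)
  hc_ids <- cohort$subject_id[cohort$group == "HC"]
  pat_ids <- cohort$subject_id[cohort$group == "patient"]

  # --- deviations -----------------------------------------------------------
  # Regions whose metric is constant across the HC cohort in a stratum (can
  # happen at reduced scale, e.g. a region with no triangles in every control
  # network) carry no normative information; they are dropped from that
  # stratum and recorded, rather than aborting the run.
  dropped <- list()
  standardize_stratum <- function(df, metric, band, density) {
    hc <- df[df$subject_id %in% hc_ids, ]
    sdv <- tapply(hc$value, hc$region_id, sd)
    bad <- as.integer(names(sdv)[!is.finite(sdv) | sdv == 0])
    if (length(bad) > 0L) {
      dropped[[length(dropped) + 1L]] <<- data.frame(
        metric = metric, band = band, density = density, region_id = bad,
        stringsAsFactors = FALSE)
      df <- df[!df$region_id %in% bad, ]
    }
    standardize_to_hc(df, hc_ids)
  }
  offset_dev <- standardize_stratum(
    data.frame(subject_id = offsets$subject_id, region_id = offsets$region_id,
               value = offsets$offset, stringsAsFactors = FALSE),
    "offset", "broadband", NA_real_)
  metric_dev <- list()
  for (b in band_names) for (dens in config$densities) {
    sub <- metrics[metrics$band == b & metrics$density == dens, ]
    for (mcol in c("cc", "ec")) {
      dv <- standardize_stratum(
        data.frame(subject_id = sub$subject_id, region_id = sub$region_id,
                   value = sub[[mcol]], stringsAsFactors = FALSE),
        mcol, b, dens)
      metric_dev[[length(metric_dev) + 1L]] <-
        cbind(metric = mcol, band = b, density = dens, dv,
              stringsAsFactors = FALSE)
    }
  }
  metric_dev <- do.call(rbind, metric_dev)

  assignments <- list()
  if (length(pat_ids) > 0L && !is.null(study$overlaps)) {
    for (sid in pat_ids) {
      ov <- study$overlaps[study$overlaps$subject_id == sid,
                           c("region_id", "overlap_fraction")]
      assignments[[sid]] <- assign_areas(ov, atlas)
    }
  }
  assign_long <- do.call(rbind, lapply(names(assignments), function(sid) {
    data.frame(subject_id = sid, assignments[[sid]],
               excluded_patient = attr(assignments[[sid]], "excluded_patient"),
               stringsAsFactors = FALSE)
  }))

  # --- area means -----------------------------------------------------------
  area_means <- list()
  area_means[[1L]] <- cbind(metric = "offset", band = "broadband", density = NA_real_,
                            area_summary(offset_dev, assignments, cohort),
                            stringsAsFactors = FALSE)
  for (b in band_names) for (dens in config$densities) for (mcol in c("cc", "ec")) {
    dv <- metric_dev[metric_dev$metric == mcol & metric_dev$band == b &
                       metric_dev$density == dens, ]
    area_means[[length(area_means) + 1L]] <-
      cbind(metric = mcol, band = b, density = dens,
            area_summary(dv, assignments, cohort), stringsAsFactors = FALSE)
  }
  area_means <- do.call(rbind, area_means)

  results <- list(offsets = offsets, graph_metrics = metrics,
                  offset_dev = offset_dev, metric_dev = metric_dev,
                  area_assignments = assign_long, area_means = area_means)
  if (length(dropped) > 0L) results$dropped_regions <- do.call(rbind, dropped)

  # --- area group tests -----------------------------------------------------
  if (isTRUE(config$run_area_tests) && length(pat_ids) > 0L) {
    blocks <- list()
    if (config$unit_of_observation == "subject_means") {
      am <- area_means
    } else {
      am <- pooled_area_values(offset_dev, metric_dev, assignments, cohort,
                               band_names, config$densities)
    }
    off_am <- am[am$metric == "offset", ]
    blocks[[1L]] <- area_test_block(off_am, "offset", "broadband", NA_real_)
    for (mcol in c("cc", "ec")) for (b in band_names) for (dens in config$densities) {
      sub <- am[am$metric == mcol & am$band == b &
                  !is.na(am$density) & am$density == dens, ]
      blocks[[length(blocks) + 1L]] <- area_test_block(sub, mcol, b, dens)
    }
    tests <- do.call(rbind, blocks)
    # FDR family: offset across its 3 area contrasts; network metrics per
    # (metric, contrast) across 3 bands x 2 densities.
    tests$p_fdr <- NA_real_
    off_rows <- tests$metric == "offset"
    tests$p_fdr[off_rows] <- fdr_bh(tests$p[off_rows])
    for (mcol in c("cc", "ec")) for (area in c("peritumoral", "homologue", "rest")) {
      rows <- tests$metric == mcol & tests$contrast == area
      if (any(rows)) tests$p_fdr[rows] <- fdr_bh(tests$p[rows])
    }
    results$area_tests <- tests
  }

  # --- within-patient tests -------------------------------------------------
  if (isTRUE(config$run_within_tests) && length(pat_ids) > 1L) {
    wt <- list()
    strata <- rbind(data.frame(metric = "offset", band = "broadband",
                               density = NA_real_, stringsAsFactors = FALSE),
                    expand.grid(metric = c("cc", "ec"), band = band_names,
                                density = config$densities,
                                stringsAsFactors = FALSE))
    for (i in seq_len(nrow(strata))) {
      st <- strata[i, ]
      am <- area_means[area_means$metric == st$metric &
                         area_means$band == st$band &
                         (is.na(st$density) |
                            (!is.na(area_means$density) &
                               area_means$density == st$density)), ]
      peri <- am$mean_dev[am$area == "peritumoral"][match(pat_ids,
                am$subject_id[am$area == "peritumoral"])]
      homo <- am$mean_dev[am$area == "homologue"][match(pat_ids,
                am$subject_id[am$area == "homologue"])]
      ok <- !is.na(peri) & !is.na(homo)
      if (sum(ok) >= 2L && any(peri[ok] != homo[ok])) {
        tst <- wilcoxon_signed_rank(peri[ok], homo[ok])
        wt[[length(wt) + 1L]] <- data.frame(
          metric = st$metric, band = st$band, density = st$density,
          statistic = tst$statistic, p = tst$p, n = tst$n,
          stringsAsFactors = FALSE)
      }
    }
    if (length(wt) > 0L) {
      wt <- do.call(rbind, wt)
      wt$p_fdr <- NA_real_
      off_rows <- wt$metric == "offset"
      if (any(off_rows)) wt$p_fdr[off_rows] <- fdr_bh(wt$p[off_rows])
      for (mcol in c("cc", "ec")) {
        rows <- wt$metric == mcol
        if (any(rows)) wt$p_fdr[rows] <- fdr_bh(wt$p[rows])
      }
      results$within_patient_tests <- wt
    }
  }

  # --- group-level spin tests on raw regional means -------------------------
  if (isTRUE(config$run_spin)) {
    sp <- list()
    spin_i <- 0L
    for (grp in unique(cohort$group)) {
      ids <- cohort$subject_id[cohort$group == grp]
      off_map <- group_mean_map(offsets, ids, "offset", n)
      for (mcol in c("cc", "ec")) for (b in band_names) for (dens in config$densities) {
        sub <- metrics[metrics$band == b & metrics$density == dens &
                         metrics$subject_id %in% ids, ]
        met_map <- group_mean_map(sub, ids, mcol, n)
        spin_i <- spin_i + 1L
        res <- spin_test(off_map, met_map, atlas,
                         n_perm = config$spin_n_perm,
                         seed = derive_seed(config$seed, 900L + spin_i),
                         method = config$spin_method)
        sp[[length(sp) + 1L]] <- data.frame(
          group = grp, metric = mcol, band = b, density = dens,
          r = res$r, p_spin = res$p_spin, n_perm = res$n_perm,
          stringsAsFactors = FALSE)
      }
    }
    sp <- do.call(rbind, sp)
    for (grp in unique(sp$group)) for (mcol in c("cc", "ec")) {
      rows <- sp$group == grp & sp$metric == mcol
      sp$p_fdr[rows] <- fdr_bh(sp$p_spin[rows])
    }
    results$spin_tests <- sp
  }

  # --- within-subject mixed models ------------------------------------------
  lmm_input <- merge_dev_tables(offset_dev, metric_dev, band_names,
                                config$densities)
  if (isTRUE(config$run_lmm)) {
    lm_rows <- list()
    for (grp in intersect(config$lmm_groups, unique(cohort$group))) {
      ids <- cohort$subject_id[cohort$group == grp]
      for (b in band_names) for (dens in config$densities) {
        dat <- lmm_input[lmm_input$band == b & lmm_input$density == dens &
                           lmm_input$subject_id %in% ids, ]
        if (grp == "patient") {
          dat <- restrict_to_area(dat, assignments, "rest")
        }
        if (nrow(dat) < 10L || length(unique(dat$subject_id)) < 2L) next
        fit <- fit_lmm(dat)
        co <- fit$coefficients
        lm_rows[[length(lm_rows) + 1L]] <- data.frame(
          group = grp, band = b, density = dens, term = co$term,
          estimate = co$estimate, ci_lo = co$ci_lo, ci_hi = co$ci_hi,
          std_beta = co$std_beta, z = co$z, p = co$p,
          n_subjects = fit$n_subjects, n_obs = fit$n_obs,
          singular = fit$singular, stringsAsFactors = FALSE)
      }
    }
    if (length(lm_rows) > 0L) {
      lmm <- do.call(rbind, lm_rows)
      lmm$p_fdr <- NA_real_
      for (grp in unique(lmm$group)) {
        rows <- lmm$group == grp & lmm$term != "(Intercept)"
        lmm$p_fdr[rows] <- fdr_bh(lmm$p[rows])
      }
      results$lmm_results <- lmm
    }
  }

  # --- per-subject correlations ---------------------------------------------
  if (isTRUE(config$run_subject_correlations)) {
    pc <- list()
    for (b in band_names) for (dens in config$densities) {
      dat <- lmm_input[lmm_input$band == b & lmm_input$density == dens &
                         lmm_input$subject_id %in% pat_ids, ]
      dat <- restrict_to_area(dat, assignments, "rest")
      if (nrow(dat) == 0L) next
      for (mcol in c("CC_dev", "EC_dev")) {
        r <- per_subject_correlation(dat, "offset_dev", mcol)
        pc[[length(pc) + 1L]] <- cbind(metric = tolower(sub("_dev", "", mcol)),
                                       band = b, density = dens, r,
                                       stringsAsFactors = FALSE)
      }
    }
    if (length(pc) > 0L) results$subject_correlations <- do.call(rbind, pc)
  }

  if (!is.null(config$out_dir)) write_results(results, config)
  invisible(results)
}

group_mean_map <- function(df, ids, col, n_regions) {
  sub <- df[df$subject_id %in% ids, ]
  m <- tapply(sub[[col]], sub$region_id, mean)
  as.numeric(m[as.character(0:(n_regions - 1L))])
}

merge_dev_tables <- function(offset_dev, metric_dev, band_names, densities) {
  out <- list()
  for (b in band_names) for (dens in densities) {
    cc <- metric_dev[metric_dev$metric == "cc" & metric_dev$band == b &
                       metric_dev$density == dens, ]
    ec <- metric_dev[metric_dev$metric == "ec" & metric_dev$band == b &
                       metric_dev$density == dens, ]
    key_cc <- paste(cc$subject_id, cc$region_id)
    key_ec <- paste(ec$subject_id, ec$region_id)
    key_off <- paste(offset_dev$subject_id, offset_dev$region_id)
    out[[length(out) + 1L]] <- data.frame(
      subject_id = offset_dev$subject_id, region_id = offset_dev$region_id,
      band = b, density = dens,
      offset_dev = offset_dev$dev,
      CC_dev = cc$dev[match(key_off, key_cc)],
      EC_dev = ec$dev[match(key_off, key_ec)],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

restrict_to_area <- function(dat, assignments, area) {
  keep <- rep(FALSE, nrow(dat))
  for (sid in unique(dat$subject_id)) {
    asg <- assignments[[sid]]
    if (is.null(asg)) next
    lab <- asg$label[match(dat$region_id, asg$region_id)]
    keep <- keep | (dat$subject_id == sid & lab == area)
  }
  dat[keep, ]
}

# Pooled-region alternative unit of observation: every region contributes one
# observation to its area's sample.
pooled_area_values <- function(offset_dev, metric_dev, assignments, cohort,
                               band_names, densities) {
  rows <- list()
  pool_one <- function(dv, metric, band, density) {
    for (s in seq_len(nrow(cohort))) {
      sid <- cohort$subject_id[s]
      sub <- dv[dv$subject_id == sid, ]
      if (cohort$group[s] == "HC") {
        rows[[length(rows) + 1L]] <<- data.frame(
          metric = metric, band = band, density = density, subject_id = sid,
          group = "HC", area = "whole_brain", mean_dev = sub$dev,
          stringsAsFactors = FALSE)
      } else {
        asg <- assignments[[sid]]
        if (is.null(asg)) next
        lab <- asg$label[match(sub$region_id, asg$region_id)]
        for (area in c("peritumoral", "homologue", "rest")) {
          vals <- sub$dev[lab == area]
          if (length(vals) == 0L) next
          rows[[length(rows) + 1L]] <<- data.frame(
            metric = metric, band = band, density = density, subject_id = sid,
            group = "patient", area = area, mean_dev = vals,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  pool_one(offset_dev, "offset", "broadband", NA_real_)
  for (b in band_names) for (dens in densities) for (mcol in c("cc", "ec")) {
    dv <- metric_dev[metric_dev$metric == mcol & metric_dev$band == b &
                       metric_dev$density == dens, ]
    pool_one(dv, mcol, b, dens)
  }
  do.call(rbind, rows)
}

write_results <- function(results, config) {
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(results)) {
    write_tsv(results[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
  }
  cfg <- config
  cfg$out_dir <- NULL
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  manifest <- list(package = "gliodev",
                   version = as.character(utils::packageVersion("gliodev")),
                   seed = config$seed,
                   config = jsonlite::fromJSON(cfg_json, simplifyVector = TRUE),
                   config_md5 = unname(tools::md5sum(tmp)),
                   tables = paste0(names(results), ".tsv"))
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Write / load a study bundle to / from a directory
#'
#' Writes `atlas.tsv`, `cohort.tsv`, `overlaps.tsv`, `acquisition.json` and
#' one binary signal file per subject under `signals/`. `load_study()` reads
#' them back into a study bundle whose signals are streamed from disk by
#' [run_pipeline()].
#'
#' @param study study bundle from [simulate_study()].
#' @param dir directory to create.
#' @return `dir` (write) / study bundle (load).
#' @export
write_study <- function(study, dir) {
  dir.create(file.path(dir, "signals"), recursive = TRUE, showWarnings = FALSE)
  write_tsv(study$atlas, file.path(dir, "atlas.tsv"))
  write_tsv(study$cohort, file.path(dir, "cohort.tsv"))
  if (!is.null(study$overlaps)) {
    write_tsv(study$overlaps, file.path(dir, "overlaps.tsv"))
  }
  jsonlite::write_json(list(sampling_rate = study$sampling_rate,
                            epoch_length = study$epoch_length,
                            seed = study$seed),
                       file.path(dir, "acquisition.json"),
                       auto_unbox = TRUE, digits = NA)
  for (sid in study$cohort$subject_id) {
    write_signal_bin(subject_signal(study, sid),
                     file.path(dir, "signals", paste0(sid, ".bin")))
  }
  invisible(dir)
}

#' @rdname write_study
#' @export
load_study <- function(dir) {
  if (!dir.exists(dir)) stop_arg("study directory not found: %s", dir)
  acq_path <- file.path(dir, "acquisition.json")
  acq <- if (file.exists(acq_path)) {
    jsonlite::read_json(acq_path, simplifyVector = TRUE)
  } else list(sampling_rate = NA, epoch_length = NA, seed = NA)
  atlas <- read_atlas_tsv(file.path(dir, "atlas.tsv"))
  cohort <- read_tsv(file.path(dir, "cohort.tsv"))
  ov_path <- file.path(dir, "overlaps.tsv")
  overlaps <- if (file.exists(ov_path)) read_tsv(ov_path) else NULL
  paths <- file.path(dir, "signals", paste0(cohort$subject_id, ".bin"))
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop_arg("missing signal file(s): %s",
             paste(head(paths[missing], 3L), collapse = ", "))
  }
  names(paths) <- cohort$subject_id
  list(atlas = atlas, cohort = cohort,
       sampling_rate = acq$sampling_rate, epoch_length = acq$epoch_length,
       overlaps = overlaps, signal_paths = as.list(paths), seed = acq$seed)
}
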