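# Synthetic-data generator: atlas geometry, tumor overlaps, signal ground
# truth (aperiodic spectrum and planted phase coupling).

test_that("mirrored atlas has involutive cross-hemisphere homologue pairing", {
  atlas <- make_atlas(105, seed = 3)
  expect_equal(nrow(atlas), 210)
  expect_equal(sum(atlas$hemisphere == "left"), 105)

  for (seed in 1:3) {
    a <- make_atlas(2, seed = seed)
    hom <- a$homologue_id
    expect_identical(hom[hom + 1L], a$region_id)          # involution
    expect_true(all(a$hemisphere[a$region_id + 1L] !=
                      a$hemisphere[hom + 1L]))            # crosses hemispheres
  }

  # homologue centroids are sagittal mirror images; all centroids unit norm
  a <- make_atlas(12, seed = 9)
  h <- match(a$homologue_id, a$region_id)
  expect_equal(a$x, -a$x[h], tolerance = 1e-12)
  expect_equal(a$y, a$y[h], tolerance = 1e-12)
  expect_equal(a$z, a$z[h], tolerance = 1e-12)
  expect_equal(sqrt(a$x^2 + a$y^2 + a$z^2), rep(1, 24), tolerance = 1e-12)
  expect_true(all(a$x[a$hemisphere == "left"] < 0))

  expect_error(make_atlas(1), "n_per_hemisphere")
  expect_identical(make_atlas(8, seed = 5), make_atlas(8, seed = 5))
})

test_that("tumor overlap tables straddle the 12% boundary and stay unilateral", {
  atlas <- make_atlas(30, seed = 1)
  ov <- make_tumor_overlap(atlas, seed = 4, n_core_regions = 5,
                           fraction_range = c(0.05, 0.9))
  nz <- ov[ov$overlap_fraction > 0, ]
  expect_equal(nrow(nz), 5)
  expect_true(any(nz$overlap_fraction >= 0.12))
  expect_true(any(nz$overlap_fraction > 0 & nz$overlap_fraction < 0.12))
  expect_true(all(ov$overlap_fraction[!ov$region_id %in% nz$region_id] == 0))
  hemi <- atlas$hemisphere[match(nz$region_id, atlas$region_id)]
  expect_length(unique(hemi), 1)
  expect_identical(ov, make_tumor_overlap(atlas, seed = 4, n_core_regions = 5,
                                          fraction_range = c(0.05, 0.9)))
  expect_error(make_tumor_overlap(atlas, seed = 1, n_core_regions = 0),
               "n_core_regions")
})

test_that("signal generator is seed-deterministic and validates coupling", {
  atlas <- make_atlas(2, seed = 1)
  entry <- list(subject_id = "s", group = "HC", n_epochs = 2,
                sampling_rate = 1250, epoch_length = 1024)
  gt <- list(offset = rep(1, 4), exponent = rep(1.5, 4), knee = 0,
             oscillators = list(pair_coupling(0, 1, 9, pi / 3, 0.5)))
  s1 <- simulate_subject(atlas, entry, gt, seed = 11)
  s2 <- simulate_subject(atlas, entry, gt, seed = 11)
  expect_identical(s1$data, s2$data)
  expect_equal(dim(s1$data), c(4, 2, 1024))

  gt_bad <- gt
  gt_bad$oscillators <- list(pair_coupling(0, 1, 9, pi / 3, 1.4))
  expect_error(simulate_subject(atlas, entry, gt_bad, seed = 1),
               "strength")
})

test_that("generated spectra track the planted aperiodic curve (R^2 > 0.95)", {
  sig <- tiny_signal(n_per_hemisphere = 2, n_epochs = 15, seed = 21,
                     offset = 1.5, exponent = 2)
  d <- sig$data
  sp <- average_spectra(lapply(seq_len(15), function(e) {
    welch_psd(d[1, e, ], sig$sampling_rate)
  }))
  sel <- sp$frequencies >= 0.5 & sp$frequencies <= 45
  emp <- log10(sp$power[sel])
  theo <- 1.5 - 2 * log10(sp$frequencies[sel])
  r2 <- 1 - sum((emp - theo)^2) / sum((emp - mean(emp))^2)
  expect_gt(r2, 0.95)

  # parameter recovery at the default patient epoch count
  offs <- subject_offsets(sig)
  expect_lt(abs(mean(offs$offset) - 1.5), 0.05)
})

test_that("planted coupling drives lower-alpha PLI well above the noise floor", {
  # Uncoupled band-limited noise has a finite-sample PLI floor of ~0.3 at
  # 3.27-s epochs (few independent phase samples in a 2-Hz band), so the
  # planted pair is asserted against that floor, not against zero.
  osc <- list(pair_coupling(0, 1, 9, pi / 3, 0.9))
  sig <- tiny_signal(n_per_hemisphere = 2, n_epochs = 15, seed = 5,
                     offset = 1.0, exponent = 1.5, oscillators = osc)
  conn <- subject_connectivity(sig, default_bands()$lower_alpha)
  expect_gte(conn$values[1, 2], 0.8)
  uncoupled <- conn$values[upper.tri(conn$values)][-1]
  expect_gte(conn$values[1, 2] - mean(uncoupled), 0.4)
  expect_lt(mean(uncoupled), 0.5)
})

test_that("planted PLI grows monotonically with coupling strength", {
  strengths <- c(0.1, 0.3, 0.6, 0.9)
  mean_pli <- sapply(strengths, function(s) {
    mean(sapply(1:3, function(seed) {
      osc <- list(pair_coupling(0, 1, 9, pi / 2, s, amplitude = 2))
      sig <- tiny_signal(n_per_hemisphere = 2, n_epochs = 6, seed = seed,
                         offset = 1.0, exponent = 1.5, oscillators = osc)
      conn <- subject_connectivity(sig, default_bands()$lower_alpha)
      conn$values[1, 2]
    }))
  })
  expect_true(all(diff(mean_pli) >= 0))
})
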