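# Control-referenced standardization ("dev" maps) and tumor-area assignment.

mk_values <- function(tab) {
  data.frame(subject_id = tab$s, region_id = tab$r, value = tab$v,
             stringsAsFactors = FALSE)
}

test_that("dev is the z-score against HC regional mean and sample SD", {
  vals <- mk_values(list(s = c("h1", "h2", "h3", "p1"),
                         r = c(0, 0, 0, 0), v = c(1, 2, 3, 4)))
  out_small <- standardize_to_hc(vals, c("h1", "h2", "h3"))
  expect_equal(out_small$dev[out_small$subject_id == "p1"], (4 - 2) / 1)

  # translation invariance of dev values under a constant shift in one region
  vals2 <- vals; vals2$value <- vals2$value + 7
  out_shift <- standardize_to_hc(vals2, c("h1", "h2", "h3"))
  expect_equal(out_shift$dev, out_small$dev)

  # HC cohort standardized against itself: per-region mean 0, sample SD 1,
  # pooled mean exactly 0
  set.seed(2)
  hc <- expand.grid(s = paste0("h", 1:6), r = 0:9)
  hc$v <- rnorm(nrow(hc))
  out <- standardize_to_hc(mk_values(hc), paste0("h", 1:6))
  per_region_mean <- tapply(out$dev, out$region_id, mean)
  per_region_sd <- tapply(out$dev, out$region_id, sd)
  expect_equal(as.numeric(per_region_mean), rep(0, 10), tolerance = 1e-12)
  expect_equal(as.numeric(per_region_sd), rep(1, 10), tolerance = 1e-12)
  expect_equal(mean(out$dev), 0, tolerance = 1e-13)

  const <- mk_values(list(s = c("h1", "h2"), r = c(0, 0), v = c(1, 1)))
  expect_error(standardize_to_hc(const, c("h1", "h2")), "region")
  expect_error(standardize_to_hc(vals, "h1"), "2 HC")
})

test_that("area assignment follows the 12% rule, mirror rule, and exclusions", {
  atlas <- make_atlas(6, seed = 1)     # 12 regions, homologue(i) = i +/- 6
  ov <- data.frame(region_id = 0:11, overlap_fraction = 0)
  ov$overlap_fraction[ov$region_id == 0] <- 0.12    # boundary inclusive
  ov$overlap_fraction[ov$region_id == 1] <- 0.119   # below threshold
  asg <- assign_areas(ov, atlas)
  lab <- asg$label[match(0:11, asg$region_id)]
  expect_equal(lab[1], "peritumoral")
  expect_equal(lab[2], "excluded")
  expect_equal(lab[7], "homologue")     # mirror of region 0 despite 0 overlap
  expect_equal(lab[8], "rest")          # mirror of the sub-threshold region
  expect_true(all(lab[c(3:6, 9:12)] == "rest"))
  expect_false(attr(asg, "excluded_patient"))
  # labels partition the regions
  expect_equal(sort(asg$region_id), 0:11)

  # bilateral tumor: peritumoral regions in both hemispheres
  ov2 <- ov
  ov2$overlap_fraction[ov2$region_id == 6] <- 0.5
  expect_true(attr(assign_areas(ov2, atlas), "excluded_patient"))
  # no region above threshold
  ov3 <- data.frame(region_id = 0:11, overlap_fraction = 0)
  expect_true(attr(assign_areas(ov3, atlas), "excluded_patient"))

  bad <- data.frame(region_id = c(0, 99), overlap_fraction = c(0.5, 0.2))
  expect_error(assign_areas(bad, atlas), "absent from the atlas")
})

test_that("area summaries are per-subject means with NA for missing areas", {
  atlas <- make_atlas(2, seed = 1)     # 4 regions
  cohort <- data.frame(subject_id = c("p1", "h1"), group = c("patient", "HC"),
                       stringsAsFactors = FALSE)
  dev_map <- data.frame(
    subject_id = rep(c("p1", "h1"), each = 4), region_id = rep(0:3, 2),
    dev = c(1, 3, 5, 7, 2, 4, 6, 8), stringsAsFactors = FALSE)
  ov <- data.frame(region_id = 0:3,
                   overlap_fraction = c(0.5, 0.3, 0, 0))  # regions 0,1 tumoral
  asg <- assign_areas(ov, atlas)
  out <- area_summary(dev_map, list(p1 = asg), cohort)
  expect_equal(out$mean_dev[out$subject_id == "p1" & out$area == "peritumoral"],
               mean(c(1, 3)))
  expect_equal(out$mean_dev[out$subject_id == "p1" & out$area == "homologue"],
               mean(c(5, 7)))
  expect_true(is.na(out$mean_dev[out$subject_id == "p1" & out$area == "rest"]))
  expect_equal(out$mean_dev[out$subject_id == "h1"], mean(c(2, 4, 6, 8)))

  # bilateral patient: peritumoral/homologue missing, rest present
  ov2 <- data.frame(region_id = 0:3, overlap_fraction = c(0.5, 0, 0.4, 0))
  asg2 <- assign_areas(ov2, atlas)
  expect_true(attr(asg2, "excluded_patient"))
  out2 <- area_summary(dev_map, list(p1 = asg2), cohort)
  expect_true(is.na(out2$mean_dev[out2$subject_id == "p1" &
                                    out2$area == "peritumoral"]))
  expect_true(is.na(out2$mean_dev[out2$subject_id == "p1" &
                                    out2$area == "homologue"]))
  expect_equal(out2$mean_dev[out2$subject_id == "p1" & out2$area == "rest"],
               mean(c(3, 7)))
})
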