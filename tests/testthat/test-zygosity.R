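test_that("arm medians summarize flat and noisy profiles correctly", {
  prof <- flat_profile()
  am <- compute_arm_medians(prof)
  expect_equal(nrow(am), 20)
  expect_true(all(am$state == "neutral"))

  prof2 <- flat_profile(c(chr2q = -0.51))
  am2 <- compute_arm_medians(prof2)
  expect_equal(am2$state[am2$arm == "chr2q"], "loss")
  expect_true(all(am2$state[am2$arm != "chr2q"] == "neutral"))

  # noisy medians concentrate: sd 0.1, 50 bins/arm, within 0.05 of truth
  truth_levels <- c(chr1p = -0.5, chr3q = 0.3)
  prof3 <- flat_profile(truth_levels, bins_per_arm = 50, noise_sd = 0.1,
                        seed = 77)
  am3 <- compute_arm_medians(prof3)
  for (a in names(truth_levels)) {
    expect_lt(abs(am3$median_log2[am3$arm == a] - truth_levels[[a]]), 0.05)
  }
  expect_lt(max(abs(am3$median_log2[!am3$arm %in% names(truth_levels)])), 0.05)
})

test_that("arms with too few bins are excluded with a warning", {
  prof <- flat_profile(bins_per_arm = 4)
  prof <- prof[!(prof$arm == "chr4p" & seq_len(nrow(prof)) %in%
                   which(prof$arm == "chr4p")[1:2]), ]
  expect_warning(am <- compute_arm_medians(prof, min_bins_per_arm = 3),
                 "chr4p")
  expect_false("chr4p" %in% am$arm)
})

test_that("anchor detection keeps single-copy losses off the target chromosome", {
  arm_calls <- data.frame(
    arm = c("chr1p", "chr2q", "chr9p", "chr9q", "chr5p"),
    chrom = c("chr1", "chr2", "chr9", "chr9", "chr5"),
    median_log2 = c(-0.5, -0.55, -1.3, -0.5, 0.01),
    n_bins = 20,
    state = c("loss", "loss", "loss", "loss", "neutral"),
    stringsAsFactors = FALSE)
  anc <- detect_anchor_arms(arm_calls, "chr9p")
  expect_setequal(anc$anchors, c("chr1p", "chr2q"))
  expect_equal(anc$m, -0.525)   # median of the two anchors

  none <- detect_anchor_arms(
    data.frame(arm = "chr1p", chrom = "chr1", median_log2 = -0.1,
               n_bins = 20, state = "neutral", stringsAsFactors = FALSE),
    "chr9p")
  expect_length(none$anchors, 0)
  expect_true(is.na(none$m))

  # a -1.4 arm is deeper than a plausible single-copy loss: excluded
  deep <- detect_anchor_arms(
    data.frame(arm = "chr1p", chrom = "chr1", median_log2 = -1.4,
               n_bins = 20, state = "loss", stringsAsFactors = FALSE),
    "chr9p")
  expect_length(deep$anchors, 0)
})

test_that("purity inversion of the single-copy level is exact and clipped", {
  expect_equal(estimate_purity(-1), 1)
  expect_equal(estimate_purity(-0.01), 0.05)   # shallow anchor clips low
  expect_equal(estimate_purity(log2(0.7)), 0.6, tolerance = 1e-12)
  expect_equal(estimate_purity(-0.515), 0.6, tolerance = 1e-3)
  expect_error(estimate_purity(0.1), "negative")
  expect_error(estimate_purity(NA_real_), "finite")
})

test_that("anchored calls classify to the nearest expected level with the intact guard", {
  m <- -0.515
  base <- flat_profile(c(chr1p = m))
  hom <- set_locus_depth(base, test_locus, -1.30)
  res <- call_zygosity_anchored(hom, test_locus, "chr1p", m)
  expect_equal(res$call, "homodel")
  expect_equal(res$levels[["homodel"]], log2(1 - estimate_purity(m)),
               tolerance = 1e-12)

  het <- set_locus_depth(base, test_locus, -0.50)
  expect_equal(call_zygosity_anchored(het, test_locus, "chr1p", m)$call,
               "heterodel")

  shallow <- set_locus_depth(base, test_locus, -0.05)
  expect_equal(call_zygosity_anchored(shallow, test_locus, "chr1p", m)$call,
               "intact")

  # shallow anchors (low purity): the guard relaxes to the midpoint so a
  # genuine shallow heterodel is still callable
  m_lo <- log2(0.85)  # purity 0.3 single-copy level, above -0.25
  lo <- set_locus_depth(flat_profile(c(chr1p = m_lo)), test_locus, m_lo)
  expect_equal(call_zygosity_anchored(lo, test_locus, "chr1p", m_lo)$call,
               "heterodel")

  # too few locus bins: fixed-threshold fallback with the low_bins flag
  narrow <- list(chrom = "chr9", start = 22.5e6, end = 24e6)  # 1 bin
  res_lb <- call_zygosity_anchored(set_locus_depth(base, narrow, -0.8),
                                   narrow, "chr1p", m)
  expect_equal(res_lb$confidence_flag, "low_bins")
  expect_equal(res_lb$call, "homodel")  # -0.8 under the fixed rule
})

test_that("homodel level is strictly deeper than the anchor level for any anchor depth", {
  for (m in seq(-1.19, -0.16, by = 0.01)) {
    prof <- set_locus_depth(flat_profile(c(chr1p = m)), test_locus, m)
    lv <- call_zygosity_anchored(prof, test_locus, "chr1p", m)$levels
    expect_gt(abs(lv[["homodel"]]), abs(lv[["heterodel"]]))
  }
})

test_that("fixed thresholds reproduce the WES rule including boundaries", {
  expect_equal(call_zygosity_fixed(-0.8), "homodel")
  expect_equal(call_zygosity_fixed(-0.5), "heterodel")
  expect_equal(call_zygosity_fixed(-0.1), "intact")
  # both boundaries belong to the shallow-deletion band
  expect_equal(call_zygosity_fixed(-0.7), "heterodel")
  expect_equal(call_zygosity_fixed(-0.35), "heterodel")
  expect_equal(call_zygosity_fixed(c(-0.71, -0.3499)),
               c("homodel", "intact"))
  expect_error(call_zygosity_fixed(Inf), "finite")
})

test_that("arm-loss extent bins in 5% increments with half-open boundaries", {
  mk_arm <- function(frac, n = 100) {
    prof <- flat_profile(bins_per_arm = n)
    idx <- which(prof$arm == "chr9p")
    k <- round(frac * n)
    if (k > 0) prof$log2_ratio[idx[seq_len(k)]] <- -1
    prof
  }
  e97 <- classify_arm_extent(mk_arm(0.97), "chr9p", deletion_level = -1)
  expect_equal(e97$bin_label, "95-100")
  expect_equal(e97$category, "broad")

  e50 <- classify_arm_extent(mk_arm(0.50), "chr9p", deletion_level = -1)
  expect_equal(e50$bin_label, "50-55")
  expect_equal(e50$category, "segmental")

  e02 <- classify_arm_extent(mk_arm(0.02), "chr9p", deletion_level = -1)
  expect_equal(e02$bin_label, "0-5")
  expect_equal(e02$category, "focal")

  e0 <- classify_arm_extent(mk_arm(0), "chr9p", deletion_level = -1)
  expect_equal(e0$fraction, 0)
  expect_equal(e0$category, "none")

  # boundary membership: 5% opens the segmental band, >95% is broad
  expect_equal(classify_arm_extent(mk_arm(0.05), "chr9p", -1)$category,
               "segmental")
  expect_equal(classify_arm_extent(mk_arm(0.05), "chr9p", -1)$bin_label,
               "5-10")
  expect_equal(classify_arm_extent(mk_arm(0.95), "chr9p", -1)$category,
               "segmental")
  expect_equal(classify_arm_extent(mk_arm(1.00), "chr9p", -1)$bin_label,
               "95-100")
  expect_equal(classify_arm_extent(mk_arm(1.00), "chr9p", -1)$category,
               "broad")
})

test_that("arm loss tables reflect simulated truth and mark unknown arms", {
  expect_equal(nrow(genome_arm_loss_table(flat_profile(), character(0))), 0)

  flat <- genome_arm_loss_table(flat_profile(), c("chr1p", "chr2q"))
  expect_true(all(!flat$loss))

  cfg <- sim_config(n_samples = 1, seed = 55, noise_sd = 0.1,
                    anchor_loss_probability = 0, always_lost_arms = "chr1p",
                    cohorts = c(a = 1))
  tr <- forced_truth(cfg, 0.8, "intact", "none")
  tr$lost_arms <- "chr1p,chr2q"
  prof <- simulate_cnv_profile(cfg, tr)
  tab <- genome_arm_loss_table(prof, c("chr1p", "chr2q", "chr5p", "chrXq"))
  expect_equal(tab$loss, c(TRUE, TRUE, FALSE, NA))
})

test_that("anchored and fixed modes agree on noise-free mid-purity profiles", {
  # at purity 0.6 the single-copy level (-0.515) sits inside the fixed
  # shallow band and the homozygous level (-1.32) below the deep cutoff
  cfg <- sim_config(n_samples = 3, seed = 60, noise_sd = 0,
                    cohorts = c(a = 3))
  tr <- forced_truth(cfg, 0.6, c("intact", "heterodel", "homodel"), "focal")
  for (i in 1:3) {
    prof <- simulate_cnv_profile(cfg, tr[i, ])
    anch <- call_zygosity(prof, cfg$locus, mode = "anchored")
    fixd <- call_zygosity(prof, cfg$locus, mode = "fixed")
    expect_equal(anch$call, fixd$call)
    expect_equal(anch$call, tr$zygosity[i])
  }
})

test_that("the set-level caller annotates mode, purity and extent per sample", {
  cfg <- sim_config(n_samples = 6, seed = 61, cohorts = c(a = 6))
  tr <- simulate_truth(cfg)
  profs <- simulate_cnv_profiles(cfg, tr)
  calls <- call_zygosity_set(profs, cfg$locus)
  expect_s3_class(calls, "zygosity_table")
  expect_equal(calls$sample_id, tr$sample_id)
  expect_true(all(calls$call %in% c("intact", "heterodel", "homodel")))
  expect_true(all(calls$extent_fraction >= 0 & calls$extent_fraction <= 1))
  expect_true(all((calls$call == "intact") ==
                    (calls$extent_category == "none")))
  anchored <- calls$mode == "anchored"
  expect_true(all(calls$purity_estimate[anchored] > 0 &
                    calls$purity_estimate[anchored] <= 1))

  # a sample with no anchor arms anywhere falls back with a flag
  cfg_na <- sim_config(n_samples = 1, seed = 62,
                       anchor_loss_probability = 0,
                       always_lost_arms = character(0), noise_sd = 0,
                       cohorts = c(a = 1))
  tr_na <- forced_truth(cfg_na, 0.9, "homodel", "focal")
  call_na <- call_zygosity(simulate_cnv_profile(cfg_na, tr_na), cfg_na$locus)
  expect_equal(call_na$mode, "fixed_threshold")
  expect_equal(call_na$confidence_flag, "no_anchor_fallback")
  expect_equal(call_na$call, "homodel")
})
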