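test_that("expected_log2 matches the purity-mixture identities and caps at the floor", {
  expect_equal(expected_log2(2, 0.7), 0)
  expect_equal(expected_log2(1, 1.0), -1)
  expect_equal(expected_log2(0, 0.5), -1)
  expect_equal(expected_log2(1, 0.6), log2(0.7))
  expect_equal(expected_log2(0, 1.0), -4)   # zero mixture hits the floor
  expect_equal(expected_log2(0, 1.0, floor = -6), -6)
  expect_error(expected_log2(1, 0), "purity")
  expect_error(expected_log2(1, 1.2), "purity")
  expect_error(expected_log2(4, 0.5), "copy_number")
})

test_that("expected_log2 is monotone in copy number and purity, with homodel deeper than heterodel", {
  for (p in seq(0.05, 1, by = 0.05)) {
    vals <- expected_log2(0:3, p)
    expect_true(all(diff(vals) > 0), info = paste("purity", p))
  }
  for (cn in c(0, 1)) {
    p <- seq(0.1, 1, by = 0.05)
    vals <- expected_log2(rep(cn, length(p)), p)
    expect_true(all(diff(vals) < 1e-12), info = paste("copy", cn))
  }
  for (p in seq(0.5, 1, by = 0.05)) {
    expect_gt(abs(expected_log2(0, p)), abs(expected_log2(1, p)))
  }
})

test_that("CNV profiles are reproducible and hit the expected depths", {
  cfg <- sim_config(n_samples = 4, seed = 21, noise_sd = 0,
                    cohorts = c(a = 4))
  tr <- forced_truth(cfg, purity = c(1, 0.6, 1, 0.6),
                     zygosity = c("homodel", "heterodel", "intact", "homodel"),
                     extent = "focal")

  p1 <- simulate_cnv_profile(cfg, tr[1, ])
  p1b <- simulate_cnv_profile(cfg, tr[1, ])
  expect_identical(p1, p1b)

  idx <- p1$chrom == cfg$locus$chrom & p1$start < cfg$locus$end &
    p1$end > cfg$locus$start
  expect_true(all(p1$log2_ratio[idx] == -4))  # pure-tumor homodel at floor

  p2 <- simulate_cnv_profile(cfg, tr[2, ])
  idx2 <- p2$chrom == cfg$locus$chrom & p2$start < cfg$locus$end &
    p2$end > cfg$locus$start
  expect_equal(median(p2$log2_ratio[idx2]), log2(0.7), tolerance = 1e-9)

  # noisy run is also seed-deterministic
  cfgn <- sim_config(n_samples = 4, seed = 21, cohorts = c(a = 4))
  expect_identical(simulate_cnv_profile(cfgn, tr[4, ]),
                   simulate_cnv_profile(cfgn, tr[4, ]))
})

test_that("expression generator is deterministic and recovers configured group means", {
  cfg <- sim_config(n_samples = 30, seed = 9)
  tr <- simulate_truth(cfg)
  expect_identical(simulate_expression(cfg, tr),
                   simulate_expression(cfg, tr))

  # near-zero dispersion, no depth variation: group means within 5%
  ex <- focalzyg:::default_expression_params()
  ex$depth_log_sd <- 0
  ex$cdkn2a_dispersion[] <- 0.01
  ex$cdkn2b_dispersion[] <- 0.01
  cfg2 <- sim_config(n_samples = 2000, seed = 10, expression = ex,
                     cohorts = c(a = 2000))
  tr2 <- simulate_truth(cfg2)
  cts <- simulate_expression(cfg2, tr2)
  grp <- ifelse(tr2$zygosity == "intact", tr2$expression_group, tr2$zygosity)
  for (g in c("homodel", "low", "high")) {
    obs <- mean(cts["CDKN2A", grp == g])
    expect_lt(abs(obs / ex$cdkn2a_mu[[g]] - 1), 0.05)
  }
})

test_that("latent copula is the sole coupling when depth and group structure are removed", {
  c0 <- simulate_expression(
    isolated_expression_config(2000, 0, seed = 31),
    simulate_truth(isolated_expression_config(2000, 0, seed = 31)))
  expect_lt(abs(cor(c0["CDKN2A", ], c0["CDKN2B", ])), 0.1)

  c8 <- simulate_expression(
    isolated_expression_config(500, 0.8, seed = 32),
    simulate_truth(isolated_expression_config(500, 0.8, seed = 32)))
  expect_lt(abs(cor(c8["CDKN2A", ], c8["CDKN2B", ]) - 0.8), 0.1)
})

test_that("survival generator: censoring limit, null behavior, determinism", {
  hz <- focalzyg:::default_hazard_params()
  hz$censor_rate <- 1e6
  cfg <- sim_config(n_samples = 100, seed = 12, hazard = hz)
  tr <- simulate_truth(cfg)
  cl <- simulate_survival(cfg, tr)
  expect_true(all(cl$event == 0))
  expect_true(all(cl$pfs_months > 0))

  # null effects: log-rank on an arbitrary split rejects at roughly
  # nominal rate over seeded replicates
  hz0 <- focalzyg:::default_hazard_params()
  hz0$log_hr[] <- 0
  rej <- vapply(1:60, function(s) {
    cfg0 <- sim_config(n_samples = 80, seed = 300 + s, hazard = hz0)
    cl0 <- simulate_survival(cfg0, simulate_truth(cfg0))
    g <- rep(c("A", "B"), length.out = 80)
    logrank(cl0$pfs_months, cl0$event, g)$p < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.15)

  expect_identical(simulate_survival(cfg, tr), simulate_survival(cfg, tr))
})
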