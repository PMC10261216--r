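# Shared builders for the test suite. Everything is generated in code;
# no binary fixtures.

# A flat synthetic profile: every arm of the default genome gets
# `bins_per_arm` bins at the level in `arm_log2` (default 0), plus
# optional Gaussian noise. The chr9p locus window used by tests sits on
# bins 10..14 of chr9p.
flat_profile <- function(arm_log2 = numeric(0), bins_per_arm = 20,
                         noise_sd = 0, seed = NULL,
                         sample_id = "T1") {
  if (!is.null(seed)) set.seed(seed)
  genome <- default_genome()
  rows <- lapply(seq_len(nrow(genome)), function(i) {
    width <- (genome$end[i] - genome$start[i]) / bins_per_arm
    start <- genome$start[i] + (seq_len(bins_per_arm) - 1) * width
    lev <- arm_log2[genome$arm_label[i]]
    if (is.na(lev)) lev <- 0
    data.frame(chrom = genome$chrom[i], start = start, end = start + width,
               log2_ratio = lev + rnorm(bins_per_arm, 0, noise_sd),
               arm = genome$arm_label[i], stringsAsFactors = FALSE)
  })
  prof <- do.call(rbind, rows)
  structure(prof, class = c("cnv_profile", "data.frame"),
            sample_id = sample_id)
}

# locus covering 5 bins of chr9p in a flat_profile with 20 bins/arm
# (chr9p spans 0-45 Mb, so bins are 2.25 Mb wide)
test_locus <- list(chrom = "chr9", start = 22.5e6, end = 33.75e6)

# override the depth of the locus bins in a profile
set_locus_depth <- function(profile, locus, value) {
  idx <- profile$chrom == locus$chrom & profile$start < locus$end &
    profile$end > locus$start
  profile$log2_ratio[idx] <- value
  profile
}

# expression config with the latent CDKN2A-CDKN2B coupling isolated:
# no per-sample depth variation and a single expression group, so the
# copula correlation is the only source of between-gene correlation
isolated_expression_config <- function(n, cor_latent, seed,
                                       high_fraction = 0) {
  ex <- focalzyg:::default_expression_params()
  ex$depth_log_sd <- 0
  ex$high_fraction <- high_fraction
  sim_config(n_samples = n, seed = seed, cor_latent = cor_latent,
             zygosity_mix = c(intact = 1, heterodel = 0, homodel = 0),
             expression = ex, cohorts = c(all = n))
}

# truth table with forced zygosity/extent/purity, for controlled
# profile generation
forced_truth <- function(config, purity, zygosity, extent) {
  tr <- simulate_truth(config)
  n <- nrow(tr)
  tr$purity <- rep_len(purity, n)
  tr$zygosity <- rep_len(zygosity, n)
  tr$extent <- rep_len(extent, n)
  tr$extent[tr$zygosity == "intact"] <- "none"
  tr
}

# hand-coded two-group log-rank chi-square (independent of survdiff):
# pooled event times, observed minus expected events in group 1,
# hypergeometric variance
logrank_stat_by_hand <- function(times, events, groups) {
  g1 <- sort(unique(groups))[1]
  ev_times <- sort(unique(times[events == 1]))
  O <- E <- V <- 0
  for (t in ev_times) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & groups == g1)
    d <- sum(events == 1 & times == t)
    d1 <- sum(events == 1 & times == t & groups == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}
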