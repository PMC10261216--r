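#' Expected log2 ratio of a purity-mixed copy-number state
#'
#' Two-component mixture of tumor (fraction `purity`, `copy_number`
#' copies) and diploid normal: `log2((p*c + 2*(1-p)) / 2)`. This is the
#' noise-free depth a bin at that state shows in a bulk profile; it is
#' what makes a homozygous deletion roughly twice as deep (in log2) as a
#' single-copy loss in the same sample only at high purity, and shallower
#' everywhere else.
#'
#' @param copy_number tumor copy number, integer in 0..3.
#' @param purity tumor cell fraction in (0, 1].
#' @param floor lower cap for the log2 ratio; also the value returned
#'   when the mixture fraction is exactly 0 (pure tumor, homozygous
#'   deletion), where the ratio would be -Inf.
#' @return expected log2 ratio (vectorized).
#' @examples
#' expected_log2(2, 0.7)   # 0: diploid is the reference
#' expected_log2(1, 1.0)   # -1
#' expected_log2(1, 0.6)   # log2(0.7) ~ -0.515
#' @export
expected_log2 <- function(copy_number, purity, floor = -4) {
  if (any(purity <= 0 | purity > 1)) {
    stop_invalid("purity must lie in (0, 1]")
  }
  if (any(!copy_number %in% 0:3)) {
    stop_invalid("copy_number must be an integer in 0..3")
  }
  mix <- (purity * copy_number + 2 * (1 - purity)) / 2
  out <- ifelse(mix <= 0, floor, pmax(log2(pmax(mix, 2^floor)), floor))
  as.numeric(out)
}

#' Draw per-sample ground truth for a synthetic cohort
#'
#' Samples purity, target-locus zygosity, deletion extent class, the set
#' of arm-level single-copy losses (anchors), the expression group of
#' deletion-intact tumors, clinical covariates, and the true log hazard
#' ratio implied by the configured effects.
#'
#' @param config a [sim_config()].
#' @return data.frame with one row per sample: `sample_id`, `cohort`,
#'   `purity`, `zygosity`, `extent`, `lost_arms` (comma-separated arm
#'   labels), `expression_group` ("high"/"low"/"n/a"), `grade`, `eor`,
#'   `molecular_group`, `true_log_hr`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "truth"))
  n <- config$n_samples
  sample_id <- sprintf("S%04d", seq_len(n))
  cohort <- rep(names(config$cohorts), config$cohorts)

  purity <- runif(n, config$purity_range[1], config$purity_range[2])
  zygosity <- sample(names(config$zygosity_mix), n, replace = TRUE,
                     prob = config$zygosity_mix)
  extent <- ifelse(zygosity == "intact", "none",
                   sample(names(config$extent_mix), n, replace = TRUE,
                          prob = config$extent_mix))

  target_chrom <- config$locus$chrom
  candidate_arms <- setdiff(config$genome$arm_label[
    config$genome$chrom != target_chrom], config$always_lost_arms)
  lost <- vapply(seq_len(n), function(i) {
    hit <- candidate_arms[runif(length(candidate_arms)) <
                            config$anchor_loss_probability]
    paste(c(config$always_lost_arms, hit), collapse = ",")
  }, character(1))

  expression_group <- ifelse(
    zygosity != "intact", "n/a",
    ifelse(runif(n) < config$expression$high_fraction, "high", "low"))

  grade <- sample(1:3, n, replace = TRUE, prob = c(0.50, 0.35, 0.15))
  eor <- sample(c("GTR", "STR"), n, replace = TRUE, prob = c(0.7, 0.3))
  molecular_group <- sample(paste0("MG", 1:4), n, replace = TRUE,
                            prob = c(0.3, 0.3, 0.2, 0.2))

  lhr <- config$hazard$log_hr
  eff <- function(name) if (name %in% names(lhr)) lhr[[name]] else 0
  true_log_hr <- eff("expr_high") * (expression_group == "high") +
    eff("heterodel") * (zygosity == "heterodel") +
    eff("homodel") * (zygosity == "homodel") +
    eff("grade2") * (grade == 2) + eff("grade3") * (grade == 3) +
    eff("eor_str") * (eor == "STR")

  data.frame(sample_id, cohort, purity, zygosity, extent,
             lost_arms = lost, expression_group, grade, eor,
             molecular_group, true_log_hr, stringsAsFactors = FALSE)
}

# Tile every chromosome of the genome with bins of bin_size (0-based
# half-open); arm assignment by bin midpoint.
tile_genome <- function(genome, bin_size) {
  per_chrom <- lapply(unique(genome$chrom), function(ch) {
    len <- max(genome$end[genome$chrom == ch])
    start <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = ch, start = start,
               end = pmin(start + bin_size, len), stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, per_chrom)
  mid <- (bins$start + bins$end) / 2
  arm <- rep(NA_character_, nrow(bins))
  for (i in seq_len(nrow(genome))) {
    sel <- bins$chrom == genome$chrom[i] & mid >= genome$start[i] &
      mid < genome$end[i]
    arm[sel] <- genome$arm_label[i]
  }
  bins$arm <- arm
  bins
}

#' Simulate one binned copy-number profile
#'
#' Bins tile each chromosome at `config$bin_size`; each bin's log2 ratio
#' is [expected_log2()] of its true copy state at the sample's purity
#' plus Gaussian noise. Arm-level losses from `truth_row$lost_arms` drop
#' to one copy. The target-arm deletion follows the extent class: focal
#' deletes only the locus window; segmental deletes a contiguous region
#' covering 25--75% of the arm and containing the locus; broad deletes
#' the whole arm. For homozygous deletions the surrounding region (if
#' any) is a single-copy loss and the locus itself drops to zero copies,
#' the nested pattern focal homozygous deletions show in practice.
#'
#' @param config a [sim_config()].
#' @param truth_row one row of [simulate_truth()].
#' @return a `cnv_profile`: data.frame (`chrom`, `start`, `end`,
#'   `log2_ratio`, `arm`) with attributes `sample_id` and `bin_size`.
#'   Reproducible: the RNG stream is derived from the master seed and the
#'   sample id.
#' @export
simulate_cnv_profile <- function(config, truth_row) {
  stopifnot(inherits(config, "sim_config"), nrow(truth_row) == 1)
  set.seed(derive_seed(config$seed, paste0("cnv:", truth_row$sample_id)))

  bins <- tile_genome(config$genome, config$bin_size)
  copy <- rep(2L, nrow(bins))

  lost_arms <- strsplit(truth_row$lost_arms, ",", fixed = TRUE)[[1]]
  lost_arms <- lost_arms[nzchar(lost_arms)]
  copy[bins$arm %in% lost_arms] <- 1L

  locus <- config$locus
  in_locus <- bins$chrom == locus$chrom & bins$start < locus$end &
    bins$end > locus$start
  if (sum(in_locus) < config$min_locus_bins) {
    stop_invalid("locus covered by fewer than min_locus_bins bins")
  }

  if (truth_row$zygosity != "intact") {
    arm_idx <- which(bins$arm == config$target_arm)
    region <- switch(truth_row$extent,
      focal = which(in_locus),
      broad = arm_idx,
      segmental = {
        n_arm <- length(arm_idx)
        li <- range(match(which(in_locus), arm_idx))
        seg_len <- max(round(runif(1, 0.25, 0.75) * n_arm), diff(li) + 2)
        lo <- max(1, li[2] - seg_len + 1)
        hi <- min(li[1], n_arm - seg_len + 1)
        s <- if (hi > lo) sample(lo:hi, 1) else lo
        arm_idx[s:(s + seg_len - 1)]
      },
      stop_invalid("unknown extent class ", truth_row$extent))
    copy[region] <- 1L
    if (truth_row$zygosity == "homodel") copy[in_locus] <- 0L
  }

  log2r <- expected_log2(copy, truth_row$purity) +
    rnorm(nrow(bins), 0, config$noise_sd)
  prof <- data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                     log2_ratio = log2r, arm = bins$arm,
                     stringsAsFactors = FALSE)
  structure(prof, class = c("cnv_profile", "data.frame"),
            sample_id = truth_row$sample_id, bin_size = config$bin_size)
}

#' @rdname simulate_cnv_profile
#' @param truth full truth table from [simulate_truth()].
#' @return [simulate_cnv_profiles()] returns a named list of
#'   `cnv_profile` objects.
#' @export
simulate_cnv_profiles <- function(config, truth) {
  out <- lapply(seq_len(nrow(truth)),
                function(i) simulate_cnv_profile(config, truth[i, ]))
  names(out) <- truth$sample_id
  out
}

#' @export
print.cnv_profile <- function(x, ...) {
  cat("Binned copy-number profile:", attr(x, "sample_id") %||% "<unnamed>",
      "\n  ", nrow(x), "bins on", length(unique(x$chrom)), "chromosomes;",
      "median log2 ratio", sprintf("%.3f", median(x$log2_ratio)), "\n")
  invisible(x)
}

#' Simulate a gene-by-sample counts matrix
#'
#' CDKN2A and CDKN2B counts are negative-binomial with group-dependent
#' means (zygosity for deleted samples; low/high expression group for
#' intact ones), coupled through a Gaussian copula with latent
#' correlation `config$cor_latent`. Filler genes share per-gene
#' log-normal means across samples so that library-size and TMM
#' normalization have something to work with; per-sample sequencing
#' depth is log-normal.
#'
#' @inheritParams simulate_cnv_profile
#' @param truth truth table from [simulate_truth()].
#' @return integer matrix, genes x samples, rownames
#'   `c("CDKN2A", "CDKN2B", "FILLER...")`, colnames sample ids.
#' @export
simulate_expression <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "expression"))
  ex <- config$expression
  n <- nrow(truth)

  group <- ifelse(truth$zygosity == "intact",
                  truth$expression_group, truth$zygosity)

  depth <- exp(rnorm(n, 0, ex$depth_log_sd))
  rho <- config$cor_latent
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  a <- qnbinom(pnorm(z1), mu = ex$cdkn2a_mu[group] * depth,
               size = 1 / ex$cdkn2a_dispersion[group])
  b <- qnbinom(pnorm(z2), mu = ex$cdkn2b_mu[group] * depth,
               size = 1 / ex$cdkn2b_dispersion[group])

  gene_mu <- exp(rnorm(ex$n_filler, ex$filler_log_mean, ex$filler_log_sd))
  filler <- matrix(
    rnbinom(ex$n_filler * n, mu = outer(gene_mu, depth),
            size = 1 / ex$filler_dispersion),
    nrow = ex$n_filler)

  counts <- rbind(a, b, filler)
  rownames(counts) <- c("CDKN2A", "CDKN2B",
                        sprintf("FILLER%03d", seq_len(ex$n_filler)))
  colnames(counts) <- truth$sample_id
  storage.mode(counts) <- "integer"
  counts
}

#' Simulate a clinical table with proportional-hazards PFS
#'
#' Event times are Weibull with the configured baseline shape/scale and a
#' per-sample log hazard ratio from `truth$true_log_hr` (expression
#' group, zygosity, grade and extent-of-resection effects). Censoring is
#' exponential with rate `config$hazard$censor_rate`; observed time is
#' the minimum of the two with the event flag set accordingly.
#'
#' @inheritParams simulate_expression
#' @return data.frame: `sample_id`, `cohort`, `grade`, `eor`,
#'   `molecular_group`, `pfs_months`, `event`.
#' @export
simulate_survival <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "survival"))
  hz <- config$hazard
  n <- nrow(truth)
  u <- runif(n)
  t_event <- hz$scale * (-log(u) / exp(truth$true_log_hr))^(1 / hz$shape)
  t_cens <- if (hz$censor_rate > 0) rexp(n, hz$censor_rate) else rep(Inf, n)
  data.frame(
    sample_id = truth$sample_id, cohort = truth$cohort,
    grade = truth$grade, eor = truth$eor,
    molecular_group = truth$molecular_group,
    pfs_months = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    stringsAsFactors = FALSE
  )
}
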