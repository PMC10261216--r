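#' Abstract two-arm genome used by the simulator
#'
#' Ten abstract chromosomes of 100 Mb each, split into a p arm
#' (0--45 Mb) and a q arm (45--100 Mb). Coordinates are 0-based
#' half-open. This is deliberately not a real genome build: the caller
#' only needs bins, arm labels and a target locus, all of which are
#' configuration. A real-locus BED can be supplied instead wherever a
#' genome or locus argument is accepted.
#'
#' @return data.frame with columns `chrom`, `arm` (p/q), `arm_label`
#'   (e.g. "chr9p"), `start`, `end`.
#' @export
default_genome <- function() {
  chroms <- paste0("chr", 1:10)
  len <- 100e6
  p_end <- 45e6
  data.frame(
    chrom = rep(chroms, each = 2),
    arm = rep(c("p", "q"), 10),
    arm_label = paste0(rep(chroms, each = 2), rep(c("p", "q"), 10)),
    start = rep(c(0, p_end), 10),
    end = rep(c(p_end, len), 10),
    stringsAsFactors = FALSE
  )
}

default_expression_params <- function() {
  list(
    n_filler = 200,
    filler_log_mean = log(150),
    filler_log_sd = 1,
    filler_dispersion = 0.3,
    depth_log_sd = 0.2,
    # NB means/dispersions for the target genes per zygosity x expression
    # group. Order homodel < low < high holds in expectation; heterodel is
    # given a large dispersion to emulate the heterogeneous expression seen
    # in single-copy losses.
    cdkn2a_mu = c(homodel = 25, heterodel = 140, low = 220, high = 750),
    cdkn2a_dispersion = c(homodel = 0.6, heterodel = 1.2, low = 0.3, high = 0.3),
    cdkn2b_mu = c(homodel = 20, heterodel = 110, low = 180, high = 620),
    cdkn2b_dispersion = c(homodel = 0.6, heterodel = 1.2, low = 0.3, high = 0.3),
    high_fraction = 0.10
  )
}

default_hazard_params <- function() {
  list(
    shape = 1.2,       # Weibull shape; >1 gives an increasing baseline hazard
    scale = 90,        # months; baseline characteristic PFS time
    log_hr = c(
      expr_high = log(2),
      heterodel = 0.5,
      homodel = 1.0,
      grade2 = 0.4,
      grade3 = 0.9,
      eor_str = 0.5
    ),
    censor_rate = 0.008  # exponential censoring, per month
  )
}

#' Simulation configuration for synthetic multi-omic cohorts
#'
#' Bundles every generative parameter for the three synthetic generators
#' (copy-number profiles, expression counts, clinical/survival tables)
#' plus the genome, target locus and cohort structure, and validates the
#' invariants they rely on. One master `seed` drives all generators;
#' per-generator and per-sample streams are derived deterministically
#' from it.
#'
#' Defaults describe a meningioma-like cohort: tumor purity between 0.4
#' and 0.95, per-bin log2-ratio noise of 0.15, a rare-deletion zygosity
#' mix (92% intact, 3% heterozygous, 5% homozygous deletion), a 2 Mb
#' target locus on the p arm of chromosome 9 of the abstract genome, and
#' a guaranteed single-copy anchor loss of chr1p (arm-level losses such
#' as 1p, 10 and 22q are near-universal companions of CDKN2A/B deletion
#' in aggressive meningiomas).
#'
#' @param n_samples number of tumors to simulate.
#' @param seed master seed (small integer).
#' @param purity_range length-2 numeric in (0, 1]: tumor purity is drawn
#'   uniformly from this interval.
#' @param noise_sd per-bin Gaussian noise SD in log2-ratio units.
#' @param bin_size bin width in bp.
#' @param genome per-arm table as returned by [default_genome()].
#' @param anchor_loss_probability per-arm probability of a single-copy
#'   arm loss on non-target chromosomes.
#' @param always_lost_arms arm labels lost in every sample (anchor
#'   guarantee); character(0) disables it.
#' @param locus list(chrom, start, end), 0-based half-open target window
#'   covering CDKN2A and CDKN2B jointly.
#' @param zygosity_mix named probabilities over intact/heterodel/homodel.
#' @param extent_mix named probabilities over focal/segmental/broad,
#'   conditional on a deletion being present.
#' @param expression list of negative-binomial parameters; see
#'   `default_expression_params()` in the source for fields.
#' @param cor_latent latent Gaussian-copula correlation between CDKN2A
#'   and CDKN2B counts within a group.
#' @param hazard list(shape, scale, log_hr, censor_rate) for the Weibull
#'   proportional-hazards PFS generator.
#' @param cohorts named integer vector of cohort sizes; must sum to
#'   `n_samples`. Default splits samples into discovery/validation.
#' @param min_locus_bins minimum bins the locus must span.
#'
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 200,
                       seed = 1L,
                       purity_range = c(0.4, 0.95),
                       noise_sd = 0.15,
                       bin_size = 2e5,
                       genome = default_genome(),
                       anchor_loss_probability = 0.15,
                       always_lost_arms = "chr1p",
                       locus = list(chrom = "chr9", start = 30e6, end = 32e6),
                       zygosity_mix = c(intact = 0.92, heterodel = 0.03, homodel = 0.05),
                       extent_mix = c(focal = 0.4, segmental = 0.4, broad = 0.2),
                       expression = default_expression_params(),
                       cor_latent = 0.8,
                       hazard = default_hazard_params(),
                       cohorts = NULL,
                       min_locus_bins = 3) {
  n_samples <- as.integer(n_samples)
  if (n_samples < 1) stop_invalid("n_samples must be >= 1")
  if (length(purity_range) != 2 || purity_range[1] > purity_range[2] ||
      purity_range[1] <= 0 || purity_range[2] > 1) {
    stop_invalid("purity_range must be an interval within (0, 1]")
  }
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  if (bin_size <= 0) stop_invalid("bin_size must be positive")

  zygosity_mix <- zygosity_mix[c("intact", "heterodel", "homodel")]
  extent_mix <- extent_mix[c("focal", "segmental", "broad")]
  if (anyNA(zygosity_mix)) stop_invalid("zygosity_mix needs intact/heterodel/homodel entries")
  if (anyNA(extent_mix)) stop_invalid("extent_mix needs focal/segmental/broad entries")
  assert_prob_mix(zygosity_mix, "zygosity_mix")
  assert_prob_mix(extent_mix, "extent_mix")

  chrom_len <- tapply(genome$end, genome$chrom, max)
  if (!locus$chrom %in% genome$chrom) {
    stop_invalid("locus chromosome ", locus$chrom, " is not in the genome")
  }
  if (locus$start < 0 || locus$end <= locus$start ||
      locus$end > chrom_len[[locus$chrom]]) {
    stop_invalid("locus must lie within its chromosome")
  }
  locus_bins <- floor(locus$end / bin_size) - floor(locus$start / bin_size)
  if (locus_bins < min_locus_bins) {
    stop_invalid("locus spans ", locus_bins, " bins; at least ",
                 min_locus_bins, " are required at bin_size ", bin_size)
  }

  # which arm holds the locus (deletion extents are defined on this arm)
  on_chrom <- genome[genome$chrom == locus$chrom, ]
  hit <- on_chrom$start <= locus$start & locus$end <= on_chrom$end
  if (!any(hit)) stop_invalid("locus must lie within a single chromosome arm")
  target_arm <- on_chrom$arm_label[hit][1]

  if (is.null(cohorts)) {
    cohorts <- c(discovery = ceiling(n_samples / 2),
                 validation = floor(n_samples / 2))
    cohorts <- cohorts[cohorts > 0]
  }
  cohorts <- vapply(cohorts, as.integer, integer(1))
  if (sum(cohorts) != n_samples) {
    stop_invalid("cohort sizes must sum to n_samples (",
                 sum(cohorts), " != ", n_samples, ")")
  }
  if (is.null(names(cohorts)) || any(names(cohorts) == "")) {
    stop_invalid("cohorts must be a named vector of sizes")
  }

  if (abs(cor_latent) > 1) stop_invalid("cor_latent must be in [-1, 1]")
  if (hazard$shape <= 0 || hazard$scale <= 0 || hazard$censor_rate < 0) {
    stop_invalid("hazard shape/scale must be positive and censor_rate >= 0")
  }
  disp <- c(expression$filler_dispersion, expression$cdkn2a_dispersion,
            expression$cdkn2b_dispersion)
  if (any(disp <= 0)) stop_invalid("NB dispersions must be > 0")

  structure(list(
    n_samples = n_samples, seed = as.integer(seed),
    purity_range = purity_range, noise_sd = noise_sd, bin_size = bin_size,
    genome = genome, anchor_loss_probability = anchor_loss_probability,
    always_lost_arms = always_lost_arms, locus = locus,
    target_arm = target_arm, zygosity_mix = zygosity_mix,
    extent_mix = extent_mix, expression = expression,
    cor_latent = cor_latent, hazard = hazard, cohorts = cohorts,
    min_locus_bins = min_locus_bins
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic multi-omic cohort configuration\n")
  cat("  samples:", x$n_samples, "in cohorts:",
      paste(sprintf("%s=%d", names(x$cohorts), x$cohorts), collapse = ", "), "\n")
  cat(sprintf("  purity U(%.2f, %.2f), bin noise sd %.3f, bin size %g bp\n",
              x$purity_range[1], x$purity_range[2], x$noise_sd, x$bin_size))
  cat(sprintf("  locus %s:%g-%g (arm %s)\n", x$locus$chrom, x$locus$start,
              x$locus$end, x$target_arm))
  cat("  zygosity mix:", paste(sprintf("%s=%.3f", names(x$zygosity_mix),
                                       x$zygosity_mix), collapse = " "), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Read / write a simulation configuration as YAML
#'
#' Only scalar and vector fields are serialized; the genome table is
#' stored as a list of columns. Round-trips through [sim_config()] so the
#' result is re-validated on read.
#'
#' @param path file path.
#' @param config a `sim_config`.
#' @return [read_sim_config()] returns a `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$genome)) {
    raw$genome <- as.data.frame(raw$genome, stringsAsFactors = FALSE)
  }
  for (fld in c("zygosity_mix", "extent_mix", "cohorts")) {
    if (!is.null(raw[[fld]])) raw[[fld]] <- unlist(raw[[fld]])
  }
  if (!is.null(raw$hazard$log_hr)) raw$hazard$log_hr <- unlist(raw$hazard$log_hr)
  for (fld in c("cdkn2a_mu", "cdkn2a_dispersion", "cdkn2b_mu",
                "cdkn2b_dispersion")) {
    if (!is.null(raw$expression[[fld]])) {
      raw$expression[[fld]] <- unlist(raw$expression[[fld]])
    }
  }
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$target_arm <- NULL  # derived; recomputed on read
  x$genome <- as.list(x$genome)
  # yaml drops names of atomic vectors; store named vectors as maps
  for (fld in c("zygosity_mix", "extent_mix", "cohorts")) {
    x[[fld]] <- as.list(x[[fld]])
  }
  x$hazard$log_hr <- as.list(x$hazard$log_hr)
  for (fld in c("cdkn2a_mu", "cdkn2a_dispersion", "cdkn2b_mu",
                "cdkn2b_dispersion")) {
    x$expression[[fld]] <- as.list(x$expression[[fld]])
  }
  yaml::write_yaml(x, path, precision = 17)  # exact double round-trip
  invisible(path)
}
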