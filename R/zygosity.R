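#' Per-arm median log2 ratios and gain/loss states
#'
#' Summarizes a binned profile to one call per chromosome arm. An arm is
#' a loss when its median log2 ratio is at or below `loss_threshold` and
#' a gain at or above `gain_threshold`; otherwise neutral. Arms covered
#' by fewer than `min_bins_per_arm` bins are excluded with a warning.
#'
#' @param profile a `cnv_profile`.
#' @param min_bins_per_arm minimum bins for an arm to be called.
#' @param loss_threshold,gain_threshold state thresholds on the median.
#' @return data.frame: `arm`, `chrom`, `median_log2`, `n_bins`, `state`.
#' @export
compute_arm_medians <- function(profile, min_bins_per_arm = 3,
                                loss_threshold = -0.15,
                                gain_threshold = 0.15) {
  if (nrow(profile) == 0) stop_invalid("profile has no bins")
  keep <- !is.na(profile$arm)
  arms <- split(seq_len(nrow(profile))[keep], profile$arm[keep])
  res <- lapply(names(arms), function(a) {
    idx <- arms[[a]]
    data.frame(arm = a, chrom = profile$chrom[idx[1]],
               median_log2 = median(profile$log2_ratio[idx]),
               n_bins = length(idx), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  small <- res$n_bins < min_bins_per_arm
  if (any(small)) {
    warning("excluding arms with < ", min_bins_per_arm, " bins: ",
            paste(res$arm[small], collapse = ", "))
    res <- res[!small, ]
  }
  res$state <- ifelse(res$median_log2 <= loss_threshold, "loss",
                      ifelse(res$median_log2 >= gain_threshold, "gain",
                             "neutral"))
  rownames(res) <- NULL
  res
}

#' Find single-copy-loss anchor arms
#'
#' Anchors are arms in loss state on chromosomes other than the target
#' chromosome whose median log2 ratio falls in `anchor_range`. The lower
#' bound excludes arm-level losses deep enough to be homozygous (which
#' are biologically rare and would corrupt the single-copy calibration);
#' the upper bound is the loss threshold. The anchor depth `m` is the
#' median of the anchor arms' medians. An empty anchor set is allowed
#' and signals fallback to fixed thresholds.
#'
#' @param arm_calls output of [compute_arm_medians()].
#' @param target_arm arm label containing the locus (its whole
#'   chromosome is excluded from anchoring).
#' @param anchor_range admissible median log2 range for an anchor arm.
#' @return list with `anchors` (character vector of arm labels) and `m`
#'   (median anchor log2; `NA` when no anchors).
#' @export
detect_anchor_arms <- function(arm_calls, target_arm,
                               anchor_range = c(-1.2, -0.15)) {
  target_chrom <- arm_calls$chrom[match(target_arm, arm_calls$arm)]
  if (is.na(target_chrom)) {
    # target arm not among callable arms; exclude by label prefix instead
    target_chrom <- sub("[pq]$", "", target_arm)
  }
  cand <- arm_calls[arm_calls$state == "loss" &
                      arm_calls$chrom != target_chrom &
                      arm_calls$median_log2 >= anchor_range[1] &
                      arm_calls$median_log2 <= anchor_range[2], ]
  list(anchors = cand$arm,
       m = if (nrow(cand)) median(cand$median_log2) else NA_real_)
}

#' Tumor purity from the single-copy-loss depth
#'
#' A single-copy loss at purity p sits at `log2(1 - p/2)`; inverting the
#' anchor depth m gives `p = 2 * (1 - 2^m)`. The estimate is clipped to
#' `[0.05, 1]`.
#'
#' @param m median anchor log2 ratio; must be negative.
#' @param clip clipping interval for the estimate.
#' @return purity estimate in `clip`.
#' @export
estimate_purity <- function(m, clip = c(0.05, 1)) {
  if (!is.finite(m) || m >= 0) {
    stop_invalid("anchor depth m must be finite and negative")
  }
  min(max(2 * (1 - 2^m), clip[1]), clip[2])
}

locus_bin_index <- function(profile, locus) {
  which(profile$chrom == locus$chrom & profile$start < locus$end &
          profile$end > locus$start)
}

#' Anchored zygosity call at a locus
#'
#' The locus depth L (median log2 ratio of locus bins) is classified to
#' the nearest of three expected levels: 0 (intact), the anchor depth m
#' (single-copy loss at this sample's purity), and `log2(1 - p_hat)`
#' floored at `floor` (homozygous deletion), where `p_hat` comes from
#' [estimate_purity()]. A noise guard calls intact whenever L is above
#' `max(m/2, noise_guard)`: at usual purities this is the fixed guard
#' (default -0.25, midway between 0 and the shallow-deletion WES bound),
#' while for shallow anchors (low purity) it falls back to the
#' intact/heterodel midpoint so genuine shallow losses are not erased.
#' Ties break toward the less extreme call (intact over heterodel over
#' homodel).
#'
#' @param profile a `cnv_profile`.
#' @param locus list(chrom, start, end), 0-based half-open.
#' @param anchors character vector of anchor arm labels.
#' @param m median anchor log2 ratio.
#' @param min_locus_bins minimum locus bins for an anchored call.
#' @param floor depth floor for the homozygous level.
#' @param noise_guard fixed component of the intact guard.
#' @return list: `call`, `locus_median_log2`, `purity_estimate`,
#'   `levels` (named expected depths), `confidence_flag`.
#' @export
call_zygosity_anchored <- function(profile, locus, anchors, m,
                                   min_locus_bins = 3, floor = -4,
                                   noise_guard = -0.25) {
  if (length(anchors) == 0 || !is.finite(m)) {
    stop_invalid("anchored calling requires a non-empty anchor set")
  }
  idx <- locus_bin_index(profile, locus)
  L <- median(profile$log2_ratio[idx])
  p_hat <- estimate_purity(m)
  levels <- c(intact = 0,
              heterodel = m,
              homodel = max(log2(max(1 - p_hat, 2^floor)), floor))
  flag <- if (length(idx) < min_locus_bins) "low_bins" else "ok"
  if (flag == "low_bins") {
    call <- call_zygosity_fixed(L)
  } else if (L > max(m / 2, noise_guard)) {
    call <- "intact"
  } else {
    d <- abs(L - levels)
    call <- names(levels)[which(d == min(d))[1]]  # ties -> less extreme
  }
  list(call = call, locus_median_log2 = L, purity_estimate = p_hat,
       levels = levels, confidence_flag = flag)
}

#' Fixed-threshold zygosity call (WES-style cutoffs)
#'
#' The published fixed rule: log2 ratio below -0.7 is a homozygous
#' (deep) deletion; between -0.7 and -0.35 inclusive a heterozygous
#' (shallow) deletion; above -0.35 intact. Both boundaries belong to the
#' heterodel band.
#'
#' @param L locus median log2 ratio (finite).
#' @return "intact", "heterodel" or "homodel" (vectorized).
#' @export
call_zygosity_fixed <- function(L) {
  if (any(!is.finite(L))) stop_invalid("L must be finite")
  ifelse(L < -0.7, "homodel", ifelse(L <= -0.35, "heterodel", "intact"))
}

#' Fraction and category of target-arm loss
#'
#' The lost fraction is the share of target-arm bins at or below the
#' midpoint between the intact level (0) and the single-copy deletion
#' level. It is reported in 5% increments (intervals half-open on the
#' right except the final \[95,100\] bin) and categorized: 0 none,
#' below 5% focal, 5--95% segmental, above 95% broad.
#'
#' @param profile a `cnv_profile`.
#' @param target_arm arm label.
#' @param deletion_level expected single-copy log2 level (anchor depth m
#'   in anchored mode).
#' @return list: `fraction`, `bin_label` (e.g. "50-55"), `category`.
#' @export
classify_arm_extent <- function(profile, target_arm, deletion_level = -0.5) {
  idx <- which(profile$arm == target_arm)
  if (length(idx) == 0) stop_invalid("target arm has no bins")
  threshold <- deletion_level / 2
  fraction <- mean(profile$log2_ratio[idx] <= threshold)
  lo <- min(floor(fraction * 20), 19) * 5
  bin_label <- paste0(lo, "-", lo + 5)
  category <- if (fraction == 0) "none"
    else if (fraction < 0.05) "focal"
    else if (fraction <= 0.95) "segmental"
    else "broad"
  list(fraction = fraction, bin_label = bin_label, category = category)
}

#' Arm loss table for arms of interest
#'
#' Boolean loss call per requested arm from [compute_arm_medians()]
#' states; arms absent from the profile are recorded as unknown (`NA`).
#'
#' @param profile a `cnv_profile`.
#' @param arms_of_interest character vector of arm labels.
#' @return data.frame: `arm`, `loss` (logical, `NA` if unknown).
#' @export
genome_arm_loss_table <- function(profile, arms_of_interest) {
  if (length(arms_of_interest) == 0) {
    return(data.frame(arm = character(0), loss = logical(0)))
  }
  calls <- compute_arm_medians(profile)
  state <- calls$state[match(arms_of_interest, calls$arm)]
  data.frame(arm = arms_of_interest, loss = state == "loss",
             stringsAsFactors = FALSE)
}

#' Call locus zygosity and target-arm loss extent for one profile
#'
#' End-to-end per-sample caller: computes arm medians, detects
#' single-copy anchor arms, estimates purity, makes the anchored
#' nearest-level zygosity call, and categorizes the extent of
#' target-arm loss. Falls back to the fixed WES-style cutoffs (mode
#' `fixed_threshold`, flag `no_anchor_fallback`) when no anchor arm is
#' available, and (flag `low_bins`) when the locus is covered by fewer
#' than `min_locus_bins` bins.
#'
#' @param profile a `cnv_profile`.
#' @param locus list(chrom, start, end) or one-row BED data.frame.
#' @param target_arm arm label holding the locus; defaults to the arm of
#'   the locus bins.
#' @param mode "auto" (anchored with fixed fallback), "anchored", or
#'   "fixed".
#' @param min_locus_bins,floor,noise_guard see
#'   [call_zygosity_anchored()].
#' @param anchor_range see [detect_anchor_arms()].
#' @return one-row data.frame of class `zygosity_call`: `sample_id`,
#'   `call`, `mode`, `locus_median_log2`, `anchor_arms`,
#'   `anchor_median_log2`, `purity_estimate`, `extent_fraction`,
#'   `extent_bin`, `extent_category`, `confidence_flag`.
#' @export
call_zygosity <- function(profile, locus,
                          target_arm = NULL,
                          mode = c("auto", "anchored", "fixed"),
                          min_locus_bins = 3, floor = -4,
                          noise_guard = -0.25,
                          anchor_range = c(-1.2, -0.15)) {
  mode <- match.arg(mode)
  if (is.data.frame(locus)) {
    locus <- list(chrom = locus$chrom[1], start = locus$start[1],
                  end = locus$end[1])
  }
  idx <- locus_bin_index(profile, locus)
  if (length(idx) == 0) stop_invalid("locus not covered by any bin")
  if (is.null(target_arm)) target_arm <- profile$arm[idx[1]]
  L <- median(profile$log2_ratio[idx])

  arm_calls <- compute_arm_medians(profile)
  anc <- detect_anchor_arms(arm_calls, target_arm, anchor_range)
  use_anchored <- mode %in% c("auto", "anchored") && length(anc$anchors) > 0
  if (mode == "anchored" && length(anc$anchors) == 0) {
    stop_invalid("no anchor arms available for sample ",
                 attr(profile, "sample_id"))
  }

  if (use_anchored) {
    res <- call_zygosity_anchored(profile, locus, anc$anchors, anc$m,
                                  min_locus_bins = min_locus_bins,
                                  floor = floor, noise_guard = noise_guard)
    call <- res$call
    mode_used <- if (res$confidence_flag == "low_bins") "fixed_threshold"
      else "anchored"
    flag <- res$confidence_flag
    purity <- res$purity_estimate
    deletion_level <- anc$m
  } else {
    call <- call_zygosity_fixed(L)
    mode_used <- "fixed_threshold"
    flag <- if (mode == "fixed") "ok" else "no_anchor_fallback"
    purity <- NA_real_
    deletion_level <- -0.5  # nominal single-copy depth for extent scoring
  }

  ext <- classify_arm_extent(profile, target_arm, deletion_level)
  if (call == "intact") {
    ext$category <- "none"
  } else if (ext$category == "none") {
    # deletion confined to sub-bin scale at the locus; still a focal event
    ext$category <- "focal"
  }

  structure(data.frame(
    sample_id = attr(profile, "sample_id") %||% NA_character_,
    call = call, mode = mode_used, locus_median_log2 = L,
    anchor_arms = paste(anc$anchors, collapse = ","),
    anchor_median_log2 = anc$m, purity_estimate = purity,
    extent_fraction = ext$fraction, extent_bin = ext$bin_label,
    extent_category = ext$category, confidence_flag = flag,
    stringsAsFactors = FALSE
  ), class = c("zygosity_call", "data.frame"))
}

#' @rdname call_zygosity
#' @param profiles named list of `cnv_profile` objects.
#' @param ... passed on to [call_zygosity()].
#' @return [call_zygosity_set()] returns a data.frame of class
#'   `zygosity_table`, one row per sample.
#' @export
call_zygosity_set <- function(profiles, locus, ...) {
  rows <- lapply(profiles, function(p) call_zygosity(p, locus, ...))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("zygosity_table", "data.frame"))
}

#' @export
print.zygosity_table <- function(x, ...) {
  cat("Zygosity calls for", nrow(x), "samples\n")
  print(table(call = x$call, mode = x$mode))
  n_fb <- sum(x$confidence_flag != "ok")
  if (n_fb > 0) cat(n_fb, "sample(s) used a fallback mode\n")
  invisible(x)
}
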