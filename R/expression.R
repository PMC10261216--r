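#' Counts-per-million normalization
#'
#' Scales each library to one million; with `factors` supplied the
#' effective library size is `colSums(counts) * factors` (TMM-adjusted
#' CPM).
#'
#' @param counts non-negative gene x sample matrix.
#' @param factors optional per-sample normalization factors.
#' @return matrix of CPM values, same dimnames as `counts`.
#' @export
cpm_normalize <- function(counts, factors = NULL) {
  lib <- colSums(counts)
  if (any(lib <= 0)) {
    bad <- colnames(counts)[lib <= 0] %||% which(lib <= 0)
    stop_invalid("zero-count library: ", paste(bad, collapse = ", "))
  }
  if (!is.null(factors)) {
    if (length(factors) != ncol(counts) || any(factors <= 0)) {
      stop_invalid("factors must be positive, one per sample")
    }
    lib <- lib * factors
  }
  t(t(counts) / lib) * 1e6
}

# 75th-percentile-of-rate reference selection: the sample whose upper
# quartile (scaled by library size) is closest to the mean upper quartile.
tmm_pick_reference <- function(counts, lib) {
  f75 <- apply(counts, 2, quantile, probs = 0.75) / lib
  if (min(f75) < 1e-20) {
    which.max(colSums(sqrt(counts)))
  } else {
    which.min(abs(f75 - mean(f75)))
  }
}

# One pairwise TMM factor: weighted trimmed mean of M-values of obs vs ref.
tmm_pair <- function(obs, ref, lib_obs, lib_ref,
                     logratio_trim = 0.3, sum_trim = 0.05,
                     do_weighting = TRUE, A_cutoff = -1e10,
                     min_shared_genes = 10) {
  shared <- sum(obs > 0 & ref > 0)
  if (shared < min_shared_genes) {
    warning("fewer than ", min_shared_genes,
            " shared expressed genes; TMM factor set to 1")
    return(1)
  }
  nO <- obs / lib_obs
  nR <- ref / lib_ref
  logR <- log2(nO / nR)                     # M-values
  absE <- (log2(nO) + log2(nR)) / 2         # A-values
  v <- (lib_obs - obs) / (lib_obs * obs) +
    (lib_ref - ref) / (lib_ref * ref)       # asymptotic binomial variance
  fin <- is.finite(logR) & is.finite(absE) & (absE > A_cutoff)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (max(abs(logR)) < 1e-6) return(1)

  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * sum_trim) + 1
  hiS <- n + 1 - loS
  keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
    (rank(absE) >= loS & rank(absE) <= hiS)
  f <- if (do_weighting) {
    sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  } else {
    mean(logR[keep], na.rm = TRUE)
  }
  if (!is.finite(f)) f <- 0
  2^f
}

#' Trimmed-mean-of-M-values (TMM) normalization factors
#'
#' Between-sample scaling factors from the weighted trimmed mean of
#' M-values against a reference sample: 30% two-sided trim on M-values,
#' 5% on A-values, inverse asymptotic-variance gene weights, and a final
#' rescaling so the factors have geometric mean 1. Genes with a zero
#' count in either member of a pair drop out of that pair (infinite M or
#' A). The automatic reference is the sample whose upper-quartile
#' expression rate is closest to the mean upper-quartile rate.
#'
#' @param counts non-negative gene x sample matrix, at least 2 samples.
#' @param reference "auto" or a column index/name.
#' @param logratio_trim,sum_trim two-sided trim fractions for M and A.
#' @param do_weighting use inverse-variance weights (TRUE) or a plain
#'   trimmed mean.
#' @return numeric vector of factors, geometric mean 1, named by sample.
#' @export
tmm_factors <- function(counts, reference = "auto",
                        logratio_trim = 0.3, sum_trim = 0.05,
                        do_weighting = TRUE) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop_invalid("TMM needs at least 2 samples")
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  lib <- colSums(counts)
  if (any(lib <= 0)) stop_invalid("every library must have positive counts")

  ref_col <- if (identical(reference, "auto")) {
    tmm_pick_reference(counts, lib)
  } else if (is.character(reference)) {
    match(reference, colnames(counts))
  } else {
    reference
  }
  if (is.na(ref_col) || ref_col < 1 || ref_col > ncol(counts)) {
    stop_invalid("invalid reference sample")
  }

  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair(counts[, j], counts[, ref_col], lib[j], lib[ref_col],
             logratio_trim = logratio_trim, sum_trim = sum_trim,
             do_weighting = do_weighting)
  }, numeric(1))
  f <- rescale_geomean(f)
  names(f) <- colnames(counts)
  f
}

#' Z-scores within cohorts
#'
#' Standardizes values separately within each cohort using the sample
#' (n-1) standard deviation, so every cohort has mean 0 and SD 1.
#'
#' @param values numeric vector.
#' @param cohort_labels cohort per value.
#' @param min_cohort_size cohorts below this size are an error.
#' @return numeric vector of Z-scores, same order as `values`.
#' @export
zscore_per_cohort <- function(values, cohort_labels, min_cohort_size = 3) {
  stopifnot(length(values) == length(cohort_labels))
  z <- numeric(length(values))
  for (co in unique(cohort_labels)) {
    sel <- cohort_labels == co
    if (sum(sel) < min_cohort_size) {
      stop_invalid("cohort ", co, " has fewer than ", min_cohort_size,
                   " samples")
    }
    s <- sd(values[sel])
    if (!is.finite(s) || s == 0) {
      stop_invalid("cohort ", co, " has zero variance")
    }
    z[sel] <- (values[sel] - mean(values[sel])) / s
  }
  z
}

#' Per-cohort CDKN2A expression Z-scores from raw counts
#'
#' CPM with TMM-adjusted library sizes, optional log2(CPM + 1)
#' transform (the default; raw-CPM Z-scores are available with
#' `log_transform = FALSE` and are sensitive to heavy right tails), then
#' cohort-wise standardization of the target gene.
#'
#' @param counts gene x sample counts matrix.
#' @param cohort_labels cohort per sample (column).
#' @param gene target gene, default "CDKN2A".
#' @param log_transform standardize log2(CPM + 1) instead of raw CPM.
#' @return named numeric vector of Z-scores per sample.
#' @export
expression_zscores <- function(counts, cohort_labels, gene = "CDKN2A",
                               log_transform = TRUE) {
  if (!gene %in% rownames(counts)) stop_invalid("gene ", gene, " not found")
  f <- tmm_factors(counts)
  cpm <- cpm_normalize(counts, factors = f)
  x <- cpm[gene, ]
  if (log_transform) x <- log2(x + 1)
  z <- zscore_per_cohort(x, cohort_labels)
  names(z) <- colnames(counts)
  z
}

#' Assign CDKN2A expression groups among deletion-intact samples
#'
#' Samples with any CDKN2A/B deletion call (heterozygous or homozygous)
#' are labeled "deleted" regardless of expression; deletion-intact
#' samples are "high" when their cohort Z-score is at least 1 (boundary
#' inclusive) and "low" otherwise.
#'
#' @param z named Z-score vector (names are sample ids).
#' @param zygosity_calls a `zygosity_table` or a named character vector
#'   of calls in intact/heterodel/homodel.
#' @param cohort_labels optional cohorts, carried through to the output.
#' @param threshold Z cutoff for "high".
#' @return data.frame: `sample_id`, `cdkn2a_z`, `group` (and `cohort` if
#'   given).
#' @export
assign_groups <- function(z, zygosity_calls, cohort_labels = NULL,
                          threshold = 1) {
  if (is.data.frame(zygosity_calls)) {
    calls <- setNames(zygosity_calls$call, zygosity_calls$sample_id)
  } else {
    calls <- zygosity_calls
  }
  ids <- names(z)
  if (is.null(ids)) stop_invalid("z must be named by sample id")
  missing <- setdiff(ids, names(calls))
  if (length(missing)) {
    stop_invalid("samples missing a zygosity call: ",
                 paste(missing, collapse = ", "))
  }
  calls <- calls[ids]
  group <- ifelse(calls %in% c("heterodel", "homodel"), "deleted",
                  ifelse(z >= threshold, "high", "low"))
  out <- data.frame(sample_id = ids, cdkn2a_z = as.numeric(z),
                    group = group, stringsAsFactors = FALSE)
  if (!is.null(cohort_labels)) out$cohort <- cohort_labels
  rownames(out) <- NULL
  out
}
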