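#' Pearson correlation with t-test p-value
#'
#' Thin wrapper over the standard correlation test; requires at least 3
#' finite pairs and nonzero variance in both variables.
#'
#' @param x,y numeric vectors of equal length.
#' @return list: `r`, `p`, `n`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("x and y differ in length")
  if (length(x) < 3) stop_invalid("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_invalid("values must be finite")
  }
  if (var(x) == 0 || var(y) == 0) stop_invalid("zero variance input")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Kruskal-Wallis test with Dunn post-hoc comparisons
#'
#' Global H (tie-corrected, via the standard test) plus Dunn's pairwise
#' z statistics from pooled rank means with the tie-adjusted variance,
#' two-sided p-values, and Benjamini-Hochberg adjustment across all
#' pairs.
#'
#' @param values numeric vector.
#' @param group_labels group per value; at least 2 groups of size >= 2.
#' @return list: `H`, `df`, `p`, and `pairwise` data.frame
#'   (`group1`, `group2`, `z`, `p`, `p_adj`).
#' @export
kruskal_dunn <- function(values, group_labels) {
  group_labels <- as.character(group_labels)
  sizes <- table(group_labels)
  if (length(sizes) < 2) stop_invalid("need at least 2 groups")
  if (any(sizes < 2)) {
    stop_invalid("every group needs n >= 2; too small: ",
                 paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  kw <- kruskal.test(values, factor(group_labels))

  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, group_labels, mean)
  n_g <- tapply(r, group_labels, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  groups <- names(rbar)
  pairs <- utils::combn(groups, 2)
  pw <- apply(pairs, 2, function(gg) {
    i <- gg[1]; j <- gg[2]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n_g[[i]] + 1 / n_g[[j]]))
    z <- (rbar[[i]] - rbar[[j]]) / se
    c(z = z, p = 2 * pnorm(-abs(z)))
  })
  pairwise <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                         z = pw["z", ], p = pw["p", ],
                         stringsAsFactors = FALSE)
  pairwise$p_adj <- p.adjust(pairwise$p, method = "BH")
  rownames(pairwise) <- NULL
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p = kw$p.value, pairwise = pairwise)
}

# agreement weight matrix for k ordered categories
kappa_weights <- function(k, weights) {
  d <- abs(outer(seq_len(k), seq_len(k), "-"))
  switch(weights,
         none = (d == 0) * 1,
         linear = 1 - d / (k - 1),
         quadratic = 1 - (d / (k - 1))^2)
}

#' Cohen's kappa for two raters, optionally weighted
#'
#' Inter-rater agreement on a shared ordinal score set:
#' `kappa = (p_o - p_e) / (1 - p_e)` with identity (unweighted), linear
#' or quadratic agreement weights, and the asymptotic 95% confidence
#' interval of Fleiss, Cohen and Everitt.
#'
#' @param ratings_a,ratings_b equal-length vectors of ordinal scores.
#' @param weights "none", "linear" or "quadratic".
#' @param categories full ordered score set (defaults to the union of
#'   observed scores); matters when a rater never uses a score.
#' @param conf_level confidence level for the interval.
#' @return list: `kappa`, `se`, `lower`, `upper`, `weights`, `n`.
#' @export
cohens_kappa <- function(ratings_a, ratings_b,
                         weights = c("none", "linear", "quadratic"),
                         categories = NULL, conf_level = 0.95) {
  weights <- match.arg(weights)
  if (length(ratings_a) != length(ratings_b)) {
    stop_invalid("rating vectors differ in length")
  }
  if (is.null(categories)) categories <- sort(unique(c(ratings_a, ratings_b)))
  a <- factor(ratings_a, levels = categories)
  b <- factor(ratings_b, levels = categories)
  if (anyNA(a) || anyNA(b)) stop_invalid("ratings outside the category set")
  n <- length(a)
  k <- length(categories)
  w <- kappa_weights(k, weights)

  p <- table(a, b) / n
  pi_ <- rowSums(p)
  pj_ <- colSums(p)
  po <- sum(w * p)
  pe <- sum(w * outer(pi_, pj_))
  kap <- (po - pe) / (1 - pe)

  # Fleiss-Cohen-Everitt asymptotic variance of weighted kappa
  wi <- as.vector(w %*% pj_)   # row-margin weighted means
  wj <- as.vector(pi_ %*% w)
  wbar <- outer(wi, rep(1, k)) + outer(rep(1, k), wj)
  num <- sum(p * (w - wbar * (1 - kap))^2) - (kap - pe * (1 - kap))^2
  se <- sqrt(max(num, 0) / (n * (1 - pe)^2))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  list(kappa = kap, se = se,
       lower = kap - zq * se, upper = min(kap + zq * se, 1),
       weights = weights, n = n)
}
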