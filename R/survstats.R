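#' Kaplan-Meier product-limit estimate
#'
#' Wraps the standard product-limit estimator and returns its step
#' function as a table, prepended with the S(0) = 1 row.
#'
#' @param times positive follow-up times.
#' @param events 1 = event, 0 = censored.
#' @return data.frame: `time`, `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) < 1) stop_invalid("need at least one subject")
  if (any(times <= 0)) stop_invalid("times must be positive")
  if (any(!events %in% c(0, 1))) stop_invalid("events must be 0/1")
  fit <- survfit(Surv(times, events) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  rbind(data.frame(time = 0, n_risk = length(times), n_event = 0,
                   n_censor = 0, surv = 1), out)
}

logrank_chisq <- function(times, events, groups) {
  sd <- survdiff(Surv(times, events) ~ groups)
  list(chisq = unname(sd$chisq), df = length(sd$n) - 1)
}

#' Log-rank test, global and pairwise
#'
#' Standard observed-minus-expected statistic over pooled event times.
#' The global p-value is chi-square by default or, for small samples, a
#' group-label permutation p (`p_method = "permutation"`). With
#' `pairwise = TRUE` all two-group tests are run and
#' Benjamini-Hochberg-adjusted.
#'
#' @param times positive follow-up times.
#' @param events 1 = event, 0 = censored.
#' @param groups group label per subject; at least 2 non-empty groups.
#' @param pairwise also compute all pairwise tests.
#' @param p_method "asymptotic" or "permutation".
#' @param n_perm permutations for the permutation p.
#' @return list: `chisq`, `df`, `p`, `p_method`, and `pairwise`
#'   data.frame (`group1`, `group2`, `chisq`, `p`, `p_adj`) when
#'   requested.
#' @export
logrank <- function(times, events, groups, pairwise = FALSE,
                    p_method = c("asymptotic", "permutation"),
                    n_perm = 10000) {
  p_method <- match.arg(p_method)
  groups <- as.character(groups)
  if (length(unique(groups)) < 2) stop_invalid("need at least 2 groups")
  obs <- logrank_chisq(times, events, groups)
  p <- if (p_method == "asymptotic") {
    pchisq(obs$chisq, obs$df, lower.tail = FALSE)
  } else {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      stat_b <- logrank_chisq(times, events, sample(groups))$chisq
      if (stat_b >= obs$chisq - 1e-12) hits <- hits + 1L
    }
    (1 + hits) / (1 + n_perm)
  }
  out <- list(chisq = obs$chisq, df = obs$df, p = p, p_method = p_method)

  if (pairwise) {
    gl <- sort(unique(groups))
    prs <- utils::combn(gl, 2)
    tab <- apply(prs, 2, function(gg) {
      sel <- groups %in% gg
      o <- logrank_chisq(times[sel], events[sel], groups[sel])
      c(chisq = o$chisq, p = pchisq(o$chisq, 1, lower.tail = FALSE))
    })
    pw <- data.frame(group1 = prs[1, ], group2 = prs[2, ],
                     chisq = tab["chisq", ], p = tab["p", ],
                     stringsAsFactors = FALSE)
    pw$p_adj <- p.adjust(pw$p, method = "BH")
    rownames(pw) <- NULL
    out$pairwise <- pw
  }
  out
}

#' Cox proportional-hazards fit
#'
#' Maximizes the partial likelihood with Efron tie handling and returns
#' per-covariate hazard ratios with Wald confidence intervals and
#' p-values. Non-convergence and separation (diverging coefficients)
#' are explicit errors.
#'
#' @param records data.frame holding time, event and covariates.
#' @param covariates character vector of covariate column names.
#' @param time,event names of the time and event columns.
#' @param ties tie handling for the partial likelihood; Efron (default)
#'   or Breslow.
#' @param conf_level Wald confidence level.
#' @return object of class `cox_fit`: list with `table` (term, coef,
#'   hr, se, lower, upper, p), `loglik`, `n`, `n_events`, and the
#'   underlying `survival::coxph` fit.
#' @export
cox_fit <- function(records, covariates, time = "pfs_months",
                    event = "event", ties = c("efron", "breslow"),
                    conf_level = 0.95) {
  ties <- match.arg(ties)
  miss <- setdiff(c(time, event, covariates), names(records))
  if (length(miss)) {
    stop_invalid("missing columns: ", paste(miss, collapse = ", "))
  }
  for (cv in covariates) {
    if (length(unique(records[[cv]])) < 2) {
      stop_invalid("constant covariate: ", cv)
    }
  }
  if (length(unique(records[[time]][records[[event]] == 1])) < 2) {
    stop_invalid("need at least 2 distinct event times")
  }
  fml <- stats::as.formula(paste0(
    "Surv(", time, ", ", event, ") ~ ",
    paste(covariates, collapse = " + ")))
  fit <- coxph(fml, data = records, ties = ties,
               control = coxph.control(eps = 1e-11, iter.max = 100))
  co <- fit$coefficients
  se <- sqrt(diag(fit$var))
  if (anyNA(co) || any(abs(co) > 15) || any(!is.finite(se))) {
    stop_invalid("Cox fit did not converge (possible separation); ",
                 "coefficients: ",
                 paste(sprintf("%s=%.2f", names(co), co), collapse = ", "))
  }
  zq <- qnorm(1 - (1 - conf_level) / 2)
  tab <- data.frame(
    term = names(co), coef = unname(co), hr = exp(unname(co)),
    se = unname(se),
    lower = exp(unname(co) - zq * se), upper = exp(unname(co) + zq * se),
    p = 2 * pnorm(-abs(unname(co) / se)),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, loglik = fit$loglik[2], n = fit$n,
                 n_events = fit$nevent, formula = fml, fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat("Cox proportional-hazards fit (Efron ties):",
      x$n, "subjects,", x$n_events, "events\n")
  tab <- x$table
  tab$hr <- sprintf(paste0("%.", digits, "f"), tab$hr)
  tab$ci <- sprintf(paste0("%.", digits, "f-%.", digits, "f"),
                    x$table$lower, x$table$upper)
  tab$p <- format.pval(x$table$p, digits = digits)
  print(tab[, c("term", "hr", "ci", "p")], row.names = FALSE)
  invisible(x)
}
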