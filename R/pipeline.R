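zygosity_levels <- c("intact", "heterodel", "homodel")

#' Aggregate deletion prevalence per cohort and overall
#'
#' Counts intact / heterozygous-deletion / homozygous-deletion calls per
#' cohort and pooled, after removing an optional exclusion set (for
#' example cases assayed by immunohistochemistry only) from both the
#' numerators and the denominator. Percentages are never stored: they
#' are recomputed from the counts by [summary.prevalence_report()] and
#' the print method, so no rounding drift can accumulate.
#'
#' @param cohort_table data.frame with `sample_id`, `cohort`,
#'   `zygosity` (one row per sample).
#' @param exclusions sample ids to drop before counting; unknown ids
#'   are an error.
#' @return object of class `prevalence_report`: data.frame with one row
#'   per cohort plus an `overall` row, columns `cohort`, `n`,
#'   `homodel`, `heterodel`, `intact`.
#' @export
aggregate_prevalence <- function(cohort_table, exclusions = NULL) {
  stopifnot(all(c("sample_id", "cohort", "zygosity") %in% names(cohort_table)))
  if (anyDuplicated(cohort_table$sample_id)) {
    stop_invalid("every sample must appear exactly once")
  }
  bad <- setdiff(cohort_table$zygosity, zygosity_levels)
  if (length(bad)) stop_invalid("unknown zygosity value: ",
                                paste(bad, collapse = ", "))
  if (!is.null(exclusions)) {
    unknown <- setdiff(exclusions, cohort_table$sample_id)
    if (length(unknown)) {
      stop_invalid("unknown exclusion sample(s): ",
                   paste(head(unknown, 5), collapse = ", "))
    }
    cohort_table <- cohort_table[!cohort_table$sample_id %in% exclusions, ]
  }
  count_block <- function(d, label) {
    z <- factor(d$zygosity, levels = zygosity_levels)
    tab <- table(z)
    data.frame(cohort = label, n = nrow(d),
               homodel = as.integer(tab[["homodel"]]),
               heterodel = as.integer(tab[["heterodel"]]),
               intact = as.integer(tab[["intact"]]),
               stringsAsFactors = FALSE)
  }
  if (nrow(cohort_table) == 0) {
    out <- data.frame(cohort = "overall", n = 0L, homodel = 0L,
                      heterodel = 0L, intact = 0L, stringsAsFactors = FALSE)
    return(structure(out, class = c("prevalence_report", "data.frame")))
  }
  per <- do.call(rbind, lapply(split(cohort_table, cohort_table$cohort),
                               function(d) count_block(d, d$cohort[1])))
  out <- rbind(per, count_block(cohort_table, "overall"))
  rownames(out) <- NULL
  structure(out, class = c("prevalence_report", "data.frame"))
}

#' @rdname aggregate_prevalence
#' @param object a `prevalence_report`.
#' @param ... unused.
#' @return [summary.prevalence_report()] returns the report with
#'   `deleted` counts and percentage columns (1 decimal) recomputed
#'   from the stored counts.
#' @export
summary.prevalence_report <- function(object, ...) {
  d <- as.data.frame(object)
  d$deleted <- d$homodel + d$heterodel
  for (col in c("homodel", "heterodel", "intact", "deleted")) {
    d[[paste0("pct_", col)]] <-
      round(100 * d[[col]] / pmax(d$n, 1), 1)
  }
  d
}

#' @export
print.prevalence_report <- function(x, ...) {
  cat("CDKN2A/B deletion prevalence\n")
  print(summary(x), row.names = FALSE)
  invisible(x)
}

#' Expand a per-cohort counts table into a per-sample cohort table
#'
#' Utility for working with published aggregate tables: takes counts of
#' homodel / heterodel / intact samples per cohort (with optional
#' `excluded_*` columns counting samples that belong to an exclusion
#' set, e.g. assayed by IHC only) and expands them into the per-sample
#' `cohort_table` that [aggregate_prevalence()] consumes, plus the
#' matching exclusion id vector.
#'
#' @param counts data.frame with columns `cohort`, `homodel`,
#'   `heterodel`, `intact` and optionally `excluded_homodel`,
#'   `excluded_heterodel`, `excluded_intact`.
#' @return list: `cohort_table` (sample_id, cohort, zygosity) and
#'   `exclusions` (character vector of sample ids).
#' @export
cohort_table_from_counts <- function(counts) {
  stopifnot(all(c("cohort", "homodel", "heterodel", "intact") %in%
                  names(counts)))
  rows <- list()
  excl <- character(0)
  for (i in seq_len(nrow(counts))) {
    co <- counts$cohort[i]
    for (zyg in zygosity_levels) {
      n_total <- counts[[zyg]][i]
      ex_col <- paste0("excluded_", zyg)
      n_ex <- if (ex_col %in% names(counts)) counts[[ex_col]][i] else 0L
      if (n_ex > n_total) stop_invalid("excluded count exceeds total for ",
                                       co, " ", zyg)
      if (n_total == 0) next
      ids <- sprintf("%s_%s_%03d", co, zyg, seq_len(n_total))
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = ids, cohort = co, zygosity = zyg,
        stringsAsFactors = FALSE)
      if (n_ex > 0) excl <- c(excl, ids[seq_len(n_ex)])
    }
  }
  list(cohort_table = do.call(rbind, rows), exclusions = excl)
}

#' Confusion matrix of called vs true zygosity
#'
#' @param truth data.frame with `sample_id`, `zygosity` (and optionally
#'   `purity`, used for stratified accuracy).
#' @param calls a `zygosity_table` or data.frame with `sample_id`,
#'   `call`.
#' @param purity_breaks cut points for purity strata.
#' @return list: `confusion` (3x3, truth rows x call columns),
#'   `accuracy`, `misclassified` (sample ids), and `by_purity` when
#'   purity is available.
#' @export
evaluate_caller <- function(truth, calls,
                            purity_breaks = c(0, 0.4, 0.6, 0.8, 1)) {
  if (!setequal(truth$sample_id, calls$sample_id)) {
    stop_invalid("truth and calls disagree on sample ids")
  }
  calls <- calls[match(truth$sample_id, calls$sample_id), ]
  tz <- factor(truth$zygosity, levels = zygosity_levels)
  cz <- factor(calls$call, levels = zygosity_levels)
  confusion <- table(truth = tz, called = cz)
  ok <- as.character(tz) == as.character(cz)
  out <- list(confusion = confusion, accuracy = mean(ok),
              misclassified = truth$sample_id[!ok])
  if ("purity" %in% names(truth)) {
    stratum <- cut(truth$purity, purity_breaks, include.lowest = TRUE)
    out$by_purity <- data.frame(
      purity = levels(stratum),
      n = as.integer(table(stratum)),
      accuracy = as.numeric(tapply(ok, stratum, mean)),
      stringsAsFactors = FALSE)
  }
  out
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' simulate -> call -> stratify -> survive, end to end: generates a
#' synthetic cohort from `config`, writes the raw inputs (SEG profiles,
#' counts TSV, clinical TSV, truth TSV, config YAML), calls zygosity
#' per sample, assigns expression groups among intact samples, runs the
#' group statistics and survival analyses, aggregates prevalence, and
#' scores the caller against the simulation truth. Every artifact is
#' written under `out_dir`; outputs are deterministic for a fixed
#' config (no timestamps), and the run log records package and R
#' versions, the seed and the config file hash.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory results: `truth`,
#'   `calls`, `assignments`, `stats`, `survival`, `prevalence`,
#'   `evaluation`, and `paths`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(out_dir, ...)

  # ---- simulate ----
  sim <- pipeline_stage("simulate", {
    truth <- simulate_truth(config)
    profiles <- simulate_cnv_profiles(config, truth)
    counts <- simulate_expression(config, truth)
    clinical <- simulate_survival(config, truth)
    if (!setequal(colnames(counts), names(profiles))) {
      stop("samples in counts and CNV profiles are inconsistent")
    }
    write_tsv(truth, path("truth.tsv"))
    write_seg(profiles, path("profiles.seg"))
    write_counts_tsv(counts, path("counts.tsv"))
    write_tsv(clinical, path("clinical.tsv"))
    write_sim_config(config, path("config.yaml"))
    list(truth = truth, profiles = profiles, counts = counts,
         clinical = clinical)
  })

  # ---- call ----
  calls <- pipeline_stage("call", {
    cl <- call_zygosity_set(sim$profiles, config$locus,
                            min_locus_bins = config$min_locus_bins)
    write_tsv(cl, path("calls.tsv"))
    jsonlite::write_json(cl, path("calls.json"), dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
    cl
  })

  # ---- stratify ----
  strat <- pipeline_stage("stratify", {
    z <- expression_zscores(sim$counts, sim$truth$cohort)
    assignments <- assign_groups(z, calls, cohort_labels = sim$truth$cohort)
    write_tsv(assignments, path("assignments.tsv"))

    lcpm <- log2(cpm_normalize(sim$counts, tmm_factors(sim$counts)) + 1)
    stats_out <- list(
      cdkn2a_cdkn2b_pearson = pearson_corr(lcpm["CDKN2A", ], lcpm["CDKN2B", ])
    )
    big <- names(which(table(calls$call) >= 2))
    if (length(big) >= 2) {
      sel <- calls$call %in% big
      stats_out$cdkn2a_by_zygosity <-
        kruskal_dunn(lcpm["CDKN2A", sel], calls$call[sel])
    }
    jsonlite::write_json(stats_out, path("stats.json"), auto_unbox = TRUE,
                         digits = NA, na = "null")
    list(assignments = assignments, stats = stats_out)
  })

  # ---- survive ----
  surv <- pipeline_stage("survive", {
    d <- merge(sim$clinical, strat$assignments[, c("sample_id", "group",
                                                   "cdkn2a_z")],
               by = "sample_id")
    d <- merge(d, data.frame(sample_id = calls$sample_id,
                             zygosity_call = calls$call,
                             stringsAsFactors = FALSE), by = "sample_id")
    km_tabs <- lapply(split(d, d$group), function(g) {
      cbind(group = g$group[1], km_estimate(g$pfs_months, g$event))
    })
    km_tab <- do.call(rbind, km_tabs)
    rownames(km_tab) <- NULL
    write_tsv(km_tab, path("km_by_group.tsv"))

    lr <- logrank(d$pfs_months, d$event, d$group, pairwise = TRUE)

    di <- d[d$group %in% c("high", "low"), ]
    di$expr_high <- as.integer(di$group == "high")
    di$grade2 <- as.integer(di$grade == 2)
    di$grade3 <- as.integer(di$grade == 3)
    di$eor_str <- as.integer(di$eor == "STR")
    cox <- cox_fit(di, c("expr_high", "grade2", "grade3", "eor_str"))
    write_tsv(cox$table, path("cox.tsv"))
    jsonlite::write_json(list(logrank = lr[c("chisq", "df", "p")],
                              cox = cox$table),
                         path("survival.json"), auto_unbox = TRUE,
                         digits = NA, na = "null")
    list(merged = d, logrank = lr, cox = cox)
  })

  # ---- prevalence + evaluation ----
  prevalence <- pipeline_stage("prevalence", {
    ct <- data.frame(sample_id = calls$sample_id,
                     cohort = sim$truth$cohort[match(calls$sample_id,
                                                     sim$truth$sample_id)],
                     zygosity = calls$call, stringsAsFactors = FALSE)
    rep <- aggregate_prevalence(ct)
    write_tsv(summary(rep), path("prevalence.tsv"))
    rep
  })
  evaluation <- pipeline_stage("evaluate", {
    ev <- evaluate_caller(sim$truth, calls)
    write_tsv(as.data.frame(ev$confusion), path("confusion.tsv"))
    ev
  })

  n_fallback <- sum(calls$confidence_flag != "ok")
  log_lines <- c(
    paste0("focalzyg ", as.character(packageVersion("focalzyg"))),
    R.version.string,
    paste0("seed: ", config$seed),
    paste0("config_md5: ", unname(md5sum(path("config.yaml")))),
    paste0("n_samples: ", config$n_samples),
    paste0("caller_accuracy: ", format(evaluation$accuracy, digits = 6)),
    paste0("fallback_mode_calls: ", n_fallback))
  writeLines(log_lines, path("run_log.txt"))
  if (n_fallback > 0) {
    message(n_fallback, " sample(s) fell back to fixed-threshold calling")
  }

  invisible(list(truth = sim$truth, calls = calls,
                 assignments = strat$assignments, stats = strat$stats,
                 survival = surv, prevalence = prevalence,
                 evaluation = evaluation, out_dir = out_dir))
}
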