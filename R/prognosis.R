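#' Maximally separated Kaplan-Meier scan for one gene
#'
#' Mirrors the best-expression-cutoff practice of pathology-atlas style
#' prognostic scans: candidate cutoffs are the expression percentiles of
#' `grid` (default 20-80% in steps of 5); at each cutoff patients split
#' into a low group (expression <= cutoff) and a high group, the two
#' Kaplan-Meier curves are compared by the log-rank test, and the cutoff
#' with the smallest p-value wins (ties go to the lower cutoff).
#' Degenerate splits (an empty group) are skipped. The scanned minimum p
#' is reported unadjusted; its null distribution is anti-conservative, so
#' the 0.001 flag threshold must be read against that (see the package
#' vignette). The direction is unfavorable when the high-expression group
#' has the lower Kaplan-Meier survival at the largest time observed in
#' both groups.
#'
#' @param expression Per-patient expression values.
#' @param time,event Survival outcome, parallel to `expression`.
#' @param grid Percentile grid within (0, 1).
#' @param alpha Flag threshold on the scanned log-rank p (default 0.001).
#' @return List with `best_cutoff`, `logrank_p`, `direction`
#'   ("unfavorable"/"favorable"), `unfavorable_flag`, `n`. All-NA result
#'   with a warning when no valid split exists (e.g. constant expression).
#' @export
best_separation_scan <- function(expression, time, event,
                                 grid = seq(0.2, 0.8, by = 0.05),
                                 alpha = 0.001) {
  stopifnot(length(expression) == length(time),
            length(time) == length(event),
            all(grid > 0 & grid < 1))
  n <- length(expression)
  if (n < 20) stop("need at least 20 patients", call. = FALSE)
  na_result <- list(best_cutoff = NA_real_, logrank_p = NA_real_,
                    direction = NA_character_, unfavorable_flag = FALSE,
                    n = n)
  cutoffs <- unique(stats::quantile(expression, probs = grid, names = FALSE))
  cutoffs <- sort(cutoffs)
  best <- NULL
  for (ct in cutoffs) {
    low <- expression <= ct
    if (all(low) || !any(low)) next
    tst <- logrank_test(data.frame(time = time[low], event = event[low]),
                        data.frame(time = time[!low], event = event[!low]))
    if (is.null(best) || tst$p_value < best$p) {
      best <- list(cutoff = ct, p = tst$p_value, low = low)
    }
  }
  if (is.null(best)) {
    warning("no valid expression split; result is NA")
    return(na_result)
  }
  low_curve <- km_estimate(time[best$low], event[best$low])
  high_curve <- km_estimate(time[!best$low], event[!best$low])
  t_common <- min(max(time[best$low]), max(time[!best$low]))
  s_low <- km_survival_at(low_curve, t_common)
  s_high <- km_survival_at(high_curve, t_common)
  direction <- if (s_high < s_low) "unfavorable" else "favorable"
  list(best_cutoff = best$cutoff,
       logrank_p = best$p,
       direction = direction,
       unfavorable_flag = direction == "unfavorable" & best$p < alpha,
       n = n)
}

#' Prognostic scan across genes (and cohorts)
#'
#' Runs [best_separation_scan()] for every gene (within every cohort when
#' a `cancer_type` column is present) of a long expression-survival table,
#' and summarises per gene: the minimum log-rank p among
#' unfavorable-direction results and the any-cohort unfavorable flag.
#'
#' @param records Long data.frame with columns gene, time, event,
#'   expression (and optionally cancer_type).
#' @param grid,alpha Passed to [best_separation_scan()].
#' @return List with `results` (one row per gene x cohort) and
#'   `gene_summary` (gene, min_unfavorable_p, unfavorable_flag).
#' @export
prognosis_layer <- function(records, grid = seq(0.2, 0.8, by = 0.05),
                            alpha = 0.001) {
  stopifnot(all(c("gene", "time", "event", "expression") %in% names(records)))
  has_cohort <- "cancer_type" %in% names(records)
  key <- if (has_cohort) {
    interaction(records$gene, records$cancer_type, drop = TRUE)
  } else {
    factor(records$gene)
  }
  pieces <- split(records, key)
  rows <- lapply(pieces, function(df) {
    scan <- suppressWarnings(
      best_separation_scan(df$expression, df$time, df$event,
                           grid = grid, alpha = alpha))
    out <- data.frame(gene = df$gene[1],
                      best_cutoff = scan$best_cutoff,
                      logrank_p = scan$logrank_p,
                      direction = scan$direction,
                      unfavorable_flag = scan$unfavorable_flag,
                      n = scan$n, stringsAsFactors = FALSE)
    if (has_cohort) out <- cbind(cancer_type = df$cancer_type[1], out,
                                 stringsAsFactors = FALSE)
    out
  })
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  genes <- sort(unique(records$gene))
  summ <- lapply(genes, function(g) {
    gr <- results[results$gene == g & !is.na(results$direction) &
                    results$direction == "unfavorable", , drop = FALSE]
    data.frame(gene = g,
               min_unfavorable_p = if (nrow(gr) > 0) min(gr$logrank_p)
                                   else NA_real_,
               unfavorable_flag = any(gr$unfavorable_flag),
               stringsAsFactors = FALSE)
  })
  gene_summary <- do.call(rbind, summ)
  rownames(gene_summary) <- NULL
  list(results = results, gene_summary = gene_summary)
}
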