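#' Partition survival records by alteration status
#'
#' A patient is altered when it carries at least one alteration call in at
#' least one essential gene. The partition of the survival records is
#' exhaustive and exclusive; patients with calls but no survival record
#' are counted and reported via the `n_excluded` attribute.
#'
#' @param calls Alteration call data.frame.
#' @param essential Non-empty character vector of essential genes.
#' @param survival Survival record data.frame (patient_id, time, event).
#' @return List with `altered` and `unaltered` survival data.frames;
#'   attribute `n_excluded` counts called patients lacking survival data.
#' @export
split_by_alteration <- function(calls, essential, survival) {
  if (length(essential) == 0) {
    stop("essential gene list must be non-empty", call. = FALSE)
  }
  stopifnot(all(c("patient_id", "gene") %in% names(calls)),
            all(c("patient_id", "time", "event") %in% names(survival)))
  altered_ids <- unique(calls$patient_id[calls$gene %in% essential])
  is_altered <- survival$patient_id %in% altered_ids
  out <- list(altered = survival[is_altered, , drop = FALSE],
              unaltered = survival[!is_altered, , drop = FALSE])
  stopifnot(nrow(out$altered) + nrow(out$unaltered) == nrow(survival))
  attr(out, "n_excluded") <-
    length(setdiff(unique(calls$patient_id), survival$patient_id))
  out
}

#' Compare overall survival between altered and unaltered patients
#'
#' Kaplan-Meier medians with log-log 95% confidence intervals per group
#' and a shared log-rank p-value.
#'
#' @param altered,unaltered Survival data.frames (time, event). Each must
#'   hold at least 2 patients and at least 1 observed event.
#' @param conf_level Confidence level for the median CI.
#' @return List with `table` (one row per group: group, n, median_os,
#'   ci_low, ci_high) and `test` (the log-rank `cr_test`).
#' @export
compare_overall_survival <- function(altered, unaltered, conf_level = 0.95) {
  for (g in list(altered, unaltered)) {
    if (nrow(g) < 2) {
      stop("each group needs at least 2 patients", call. = FALSE)
    }
    if (sum(g$event) < 1) {
      stop("each group needs at least 1 observed event", call. = FALSE)
    }
  }
  one <- function(df, label) {
    med <- km_median(km_estimate(df$time, df$event), conf_level)
    data.frame(group = label, n = nrow(df), median_os = med$median,
               ci_low = med$ci_low, ci_high = med$ci_high,
               stringsAsFactors = FALSE)
  }
  list(table = rbind(one(altered, "altered"), one(unaltered, "unaltered")),
       test = logrank_test(altered, unaltered))
}
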