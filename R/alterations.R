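#' Count alteration events per gene, cohort and type
#'
#' An event is one distinct (patient, gene, alteration type) triple: a
#' patient carrying two alteration types in the same gene contributes two
#' events. Input calls are deduplicated first, so the total event count
#' equals the number of distinct triples.
#'
#' @param calls data.frame of alteration calls (see
#'   [read_alteration_calls()]).
#' @return data.frame with gene, cancer_type, alteration_type, n_events.
#' @export
count_events <- function(calls) {
  stopifnot(all(c("patient_id", "cancer_type", "gene", "alteration_type")
                %in% names(calls)))
  calls <- unique(calls[c("patient_id", "cancer_type", "gene",
                          "alteration_type")])
  if (nrow(calls) == 0) {
    return(data.frame(gene = character(0), cancer_type = character(0),
                      alteration_type = character(0), n_events = integer(0),
                      stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(list(n_events = calls$patient_id),
                          by = calls[c("gene", "cancer_type",
                                       "alteration_type")],
                          FUN = length)
  agg <- agg[order(agg$gene, agg$cancer_type, agg$alteration_type), ]
  rownames(agg) <- NULL
  agg
}

#' Normalize alteration counts into frequencies
#'
#' The alteration frequency is `f = n_events / n_patients` for each
#' (gene, cohort, type). Gene x cohort combinations with no events count
#' as f = 0, so every per-gene and per-type mean averages over the full
#' cohort table (and, when a gene universe is supplied, over the full gene
#' set). Returns a `frequency_table`: the per-type frequencies plus the
#' per-gene means (over cohorts, all types combined) and per-type means
#' (over genes and cohorts).
#'
#' @param counts Output of [count_events()].
#' @param cohorts data.frame with cancer_type, n_patients.
#' @param genes Optional character vector giving the full gene universe;
#'   defaults to the genes present in `counts`.
#' @return A list of class `frequency_table` with elements `per_type`,
#'   `gene_means`, `type_means`, `cohorts`, `genes`.
#' @export
normalize_frequency <- function(counts, cohorts, genes = NULL) {
  stopifnot(all(c("gene", "cancer_type", "alteration_type", "n_events")
                %in% names(counts)))
  unknown <- setdiff(counts$cancer_type, cohorts$cancer_type)
  if (length(unknown) > 0) {
    stop("cohort(s) absent from the cohort table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(genes)) genes <- sort(unique(counts$gene))
  genes <- sort(unique(genes))
  n_pat <- stats::setNames(cohorts$n_patients, cohorts$cancer_type)
  per_type <- counts
  per_type$f <- per_type$n_events / n_pat[per_type$cancer_type]
  n_cohorts <- nrow(cohorts)

  ## per-gene mean f over all cohorts, all alteration types combined
  gene_tot <- stats::aggregate(list(f = per_type$f),
                               by = per_type[c("gene", "cancer_type")],
                               FUN = sum)
  gsum <- tapply(gene_tot$f, gene_tot$gene, sum)
  mean_f_gene <- stats::setNames(rep(0, length(genes)), genes)
  mean_f_gene[names(gsum)] <- gsum / n_cohorts
  gene_means <- data.frame(gene = genes,
                           mean_f_gene = unname(mean_f_gene[genes]),
                           stringsAsFactors = FALSE)

  ## per-type mean f over the full gene x cohort grid (zero-imputed)
  tsum <- tapply(per_type$f, per_type$alteration_type, sum)
  types <- alteration_types()
  mean_f_type <- stats::setNames(rep(0, length(types)), types)
  mean_f_type[names(tsum)] <- tsum / (length(genes) * n_cohorts)
  type_means <- data.frame(alteration_type = types,
                           mean_f_type = unname(mean_f_type),
                           stringsAsFactors = FALSE)

  structure(list(per_type = per_type, gene_means = gene_means,
                 type_means = type_means, cohorts = cohorts, genes = genes),
            class = "frequency_table")
}

#' Select the most altered genes by the mean-frequency cutoff
#'
#' The cutoff is the arithmetic mean, over genes, of the per-gene mean
#' alteration frequency; genes strictly above the cutoff are selected.
#' When requested, the selection is validated by a Mann-Whitney U test
#' comparing per-gene mean frequencies above vs below the cutoff.
#'
#' @param freq A `frequency_table`.
#' @param validate Run the above-vs-below Mann-Whitney validation test.
#' @return List with `cutoff`, `selected` (character vector) and, when
#'   validated, `test` (a `cr_test`).
#' @export
select_altered_genes <- function(freq, validate = FALSE) {
  stopifnot(inherits(freq, "frequency_table"))
  gm <- freq$gene_means
  if (nrow(gm) < 2) stop("need at least 2 genes", call. = FALSE)
  cutoff <- mean(gm$mean_f_gene)
  selected <- sort(gm$gene[gm$mean_f_gene > cutoff])
  out <- list(cutoff = cutoff, selected = selected)
  if (validate && length(selected) > 0 && length(selected) < nrow(gm)) {
    above <- gm$mean_f_gene[gm$gene %in% selected]
    below <- gm$mean_f_gene[!(gm$gene %in% selected)]
    out$test <- mann_whitney_u(above, below)
  }
  out
}

#' Compare each alteration type against the pooled others
#'
#' For each of the six alteration types, the per-(gene, cohort)
#' frequencies of that type (zero-imputed over the full grid) are compared
#' against the pooled frequencies of the other five types by the
#' Mann-Whitney U test, with a Bonferroni family of m = 6 comparisons.
#'
#' @param freq A `frequency_table`.
#' @param alpha Family-wise significance level (default 0.001).
#' @return data.frame with one row per type: statistic, p_value, n1, n2,
#'   alpha_adjusted, significant.
#' @export
compare_alteration_types <- function(freq, alpha = 0.001) {
  stopifnot(inherits(freq, "frequency_table"))
  types <- alteration_types()
  grid_n <- length(freq$genes) * nrow(freq$cohorts)
  ## zero-imputed f vector per type over the full gene x cohort grid
  fvec <- lapply(types, function(t) {
    rows <- freq$per_type[freq$per_type$alteration_type == t, ]
    v <- rep(0, grid_n)
    if (nrow(rows) > 0) {
      key <- match(paste(rows$gene, rows$cancer_type),
                   paste(rep(freq$genes, each = nrow(freq$cohorts)),
                         rep(freq$cohorts$cancer_type,
                             times = length(freq$genes))))
      v[key] <- rows$f
    }
    v
  })
  names(fvec) <- types
  if (sum(vapply(fvec, function(v) any(v > 0), logical(1))) < 2) {
    stop("need at least 2 alteration types with events", call. = FALSE)
  }
  m <- length(types)
  res <- lapply(types, function(t) {
    x <- fvec[[t]]
    y <- unlist(fvec[setdiff(types, t)], use.names = FALSE)
    tst <- suppressWarnings(mann_whitney_u(x, y))
    data.frame(alteration_type = t, statistic = tst$statistic,
               p_value = tst$p_value, n1 = tst$n1, n2 = tst$n2,
               alpha_adjusted = alpha / m,
               significant = tst$p_value < alpha / m,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Rank cohorts by mean alteration frequency
#'
#' Per cohort, the mean over genes of the all-types-combined frequency
#' (zero-imputed over the gene universe), in descending order with
#' alphabetical tie-breaking. With `annotations` and `category` the mean
#' is restricted to genes of one category.
#'
#' @param freq A `frequency_table`.
#' @param annotations Optional gene annotation data.frame.
#' @param category Optional category (CCC / CCG / NMCRE) to restrict to.
#' @return data.frame with cancer_type, mean_f, ordered best first.
#' @export
rank_cohorts <- function(freq, annotations = NULL, category = NULL) {
  stopifnot(inherits(freq, "frequency_table"))
  genes <- freq$genes
  if (!is.null(category)) {
    stopifnot(!is.null(annotations), category %in% gene_categories())
    genes <- intersect(genes,
                       annotations$gene[annotations$category == category])
  }
  per <- freq$per_type[freq$per_type$gene %in% genes, ]
  csum <- tapply(per$f, per$cancer_type, sum)
  mean_f <- stats::setNames(rep(0, nrow(freq$cohorts)),
                            freq$cohorts$cancer_type)
  mean_f[names(csum)] <- csum / length(genes)
  out <- data.frame(cancer_type = names(mean_f), mean_f = unname(mean_f),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_f, out$cancer_type), ]
  rownames(out) <- NULL
  out
}

#' Category composition of a gene set
#'
#' Counts and percentages of CCC / CCG / NMCRE genes within a set.
#' Percentages are exact (`100 * n / total`); rounding is left to the
#' report stage.
#'
#' @param genes Character vector of gene symbols.
#' @param annotations Gene annotation data.frame covering every gene.
#' @return data.frame with category, n, pct.
#' @export
category_breakdown <- function(genes, annotations) {
  if (length(genes) == 0) {
    warning("empty gene set; all categories zero")
    return(data.frame(category = gene_categories(), n = 0L, pct = 0,
                      stringsAsFactors = FALSE))
  }
  missing <- setdiff(genes, annotations$gene)
  if (length(missing) > 0) {
    stop("unannotated gene(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cat_of <- stats::setNames(annotations$category, annotations$gene)
  n <- table(factor(cat_of[genes], levels = gene_categories()))
  data.frame(category = gene_categories(), n = as.integer(n),
             pct = 100 * as.integer(n) / length(genes),
             stringsAsFactors = FALSE)
}

#' Run the full alteration layer
#'
#' Counts events, normalizes frequencies over the cohort table and gene
#' universe, selects genes above the mean-frequency cutoff (with
#' Mann-Whitney validation), compares alteration types, and ranks cohorts.
#'
#' @param calls Alteration calls.
#' @param cohorts Cohort table.
#' @param annotations Gene annotations (defines the gene universe).
#' @param alpha Significance level for the type comparison.
#' @return List with `freq`, `selection`, `type_tests`, `cohort_ranking`,
#'   `total_events`.
#' @export
alteration_layer <- function(calls, cohorts, annotations, alpha = 0.001) {
  counts <- count_events(calls)
  freq <- normalize_frequency(counts, cohorts, genes = annotations$gene)
  selection <- select_altered_genes(freq, validate = TRUE)
  type_tests <- compare_alteration_types(freq, alpha = alpha)
  list(freq = freq,
       selection = selection,
       type_tests = type_tests,
       cohort_ranking = rank_cohorts(freq),
       total_events = sum(counts$n_events))
}
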