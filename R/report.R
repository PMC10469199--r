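#' Round half away from zero
#'
#' Commercial rounding (0.5 rounds up in magnitude), the convention used
#' for every printed percentage, as opposed to the IEEE round-half-even of
#' base [round()].
#'
#' @param x Numeric.
#' @param digits Decimal places (default 0).
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

## internal: count/percentage block for one gene set
tally_gene_set <- function(label, genes, annotations, universe_n) {
  n <- length(genes)
  rows <- data.frame(
    metric = c(paste0("n_", label), paste0("pct_", label)),
    value = c(n, if (universe_n > 0)
                    round_half_up(100 * n / universe_n, 1) else NA_real_),
    stringsAsFactors = FALSE)
  if (n > 0) {
    bd <- category_breakdown(genes, annotations)
    cat_rows <- data.frame(
      metric = c(paste0("n_", label, "_", tolower(bd$category)),
                 paste0("pct_", label, "_", tolower(bd$category))),
      value = c(bd$n, round_half_up(bd$pct, 0)),
      stringsAsFactors = FALSE)
    rows <- rbind(rows, cat_rows)
  }
  rows
}

#' Summary tally of the pipeline outputs
#'
#' Recomputes every headline count and percentage from the emitted layer
#' outputs: total patients (sum of cohort sizes), total genes (sum of
#' category sizes), total alteration events, and count plus percentage
#' (of the gene universe, one decimal) and per-category composition
#' (nearest integer percent) for the selected, unfavorable,
#' hallmark-reachable and essential gene sets. Percentages use
#' round-half-away-from-zero. Empty denominators yield NA.
#'
#' @param cohorts Cohort table.
#' @param annotations Gene annotation table (the gene universe).
#' @param total_events Total alteration event count (optional).
#' @param selected,unfavorable,reachable,essential Optional character
#'   vectors of gene symbols.
#' @return data.frame with columns metric, value.
#' @export
tally_report <- function(cohorts, annotations, total_events = NULL,
                         selected = NULL, unfavorable = NULL,
                         reachable = NULL, essential = NULL) {
  n_genes <- nrow(annotations)
  cat_n <- table(factor(annotations$category, levels = gene_categories()))
  rows <- data.frame(
    metric = c("total_patients", "total_cohorts", "total_genes",
               paste0("n_genes_", tolower(gene_categories()))),
    value = c(sum(cohorts$n_patients), nrow(cohorts), n_genes,
              as.integer(cat_n)),
    stringsAsFactors = FALSE)
  if (!is.null(total_events)) {
    rows <- rbind(rows, data.frame(metric = "total_events",
                                   value = total_events))
  }
  sets <- list(selected = selected, unfavorable = unfavorable,
               reachable = reachable, essential = essential)
  for (label in names(sets)) {
    if (!is.null(sets[[label]])) {
      rows <- rbind(rows,
                    tally_gene_set(label, sets[[label]], annotations,
                                   n_genes))
    }
  }
  rownames(rows) <- NULL
  rows
}

#' Run the full prioritization pipeline on a simulation configuration
#'
#' Executes, in order: alteration-call simulation and the alteration
#' layer; interactome simulation and the network layer; per-gene
#' expression-survival simulation and the prognostic scan; causal-graph
#' simulation and the hallmark layer; CR-cancer score integration with
#' essential-gene selection; the metastatic overall-survival comparison;
#' and the summary tally. Every stage is deterministic given the config
#' seed. When `outdir` is given, all tables plus a JSON run manifest are
#' written there.
#'
#' @param config A `sim_config`.
#' @param outdir Optional output directory.
#' @param policy,combine,missing Score-integration policies (see
#'   [integrate_scores()]).
#' @return List with elements `alteration`, `network`, `prognosis`,
#'   `hallmark`, `scores`, `essential`, `survival`, `tally`, `manifest`.
#' @export
run_pipeline <- function(config, outdir = NULL,
                         policy = "rank_then_cut", combine = "mean",
                         missing = "exclude") {
  stopifnot(inherits(config, "sim_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage ", dQuote(name), " failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  genes <- config$genes$gene

  calls <- stage("simulate_alterations", gen_alteration_calls(config))
  alt <- stage("alteration_layer",
               alteration_layer(calls, config$cohorts, config$genes))
  message("alterations: ", nrow(calls), " calls -> ",
          length(alt$selection$selected), " genes above cutoff ",
          signif(alt$selection$cutoff, 3))

  ppi <- stage("simulate_ppi", gen_ppi_edges(config))
  net <- stage("network_layer",
               network_layer(ppi, config$genes, config$driver_proteins))
  message("network: ", nrow(ppi), " edges -> ",
          nrow(net$network$nodes), " nodes retained")

  expr_records <- stage("simulate_expression_survival", {
    do.call(rbind, lapply(genes, function(g) {
      cbind(gene = g, gen_survival_cohort(config, "expression", gene = g),
            stringsAsFactors = FALSE)
    }))
  })
  prog <- stage("prognosis_layer", prognosis_layer(expr_records))
  message("prognosis: ",
          sum(prog$gene_summary$unfavorable_flag), " unfavorable gene(s)")

  causal <- stage("simulate_causal_graph", gen_causal_graph(config))
  hm <- stage("hallmark_layer",
              hallmark_layer(causal, genes, config$phenotypes))
  reachable <- names(hm$min_distance)[!is.na(hm$min_distance)]
  message("hallmarks: ", length(reachable), " of ", length(genes),
          " proteins reach a phenotype")

  cr_degree <- with(net$centrality,
                    stats::setNames(degree[is_cr], node[is_cr]))
  unfav <- prog$gene_summary
  prognosis_value <- stats::setNames(unfav$min_unfavorable_p, unfav$gene)
  scores <- stage("score_integration", {
    sm <- build_score_matrix(
      genes,
      alteration = stats::setNames(alt$freq$gene_means$mean_f_gene,
                                   alt$freq$gene_means$gene),
      network = cr_degree,
      prognosis = prognosis_value,
      hallmark = hm$min_distance)
    integrate_scores(sm, policy = policy, combine = combine,
                     missing = missing)
  })
  ess <- essential_genes(scores)
  message("integration: ", length(ess), " essential gene(s)")

  os <- stage("simulate_os_cohort", gen_survival_cohort(config, "altered"))
  surv <- stage("survival_comparison",
                compare_overall_survival(os[os$altered, , drop = FALSE],
                                         os[!os$altered, , drop = FALSE]))

  tally <- stage("report", tally_report(
    config$cohorts, config$genes, total_events = alt$total_events,
    selected = alt$selection$selected,
    unfavorable = unfav$gene[unfav$unfavorable_flag],
    reachable = reachable,
    essential = ess))

  manifest <- list(
    seed = config$seed,
    tool_version = as.character(utils::packageVersion("chronoprio")),
    policies = list(integration = policy, combine = combine,
                    missing_layers = missing,
                    event_counting = "per_type",
                    ppi_cutoff = 0.9, essential_cutoff = 0.9,
                    prognosis_alpha = 0.001),
    n_genes = length(genes),
    n_patients = sum(config$cohorts$n_patients))

  result <- list(alteration = alt, network = net, prognosis = prog,
                 hallmark = hm, scores = scores, essential = ess,
                 survival = surv, tally = tally, manifest = manifest)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_table(alt$freq$gene_means, file.path(outdir, "gene_mean_f.tsv"))
    write_table(alt$type_tests, file.path(outdir, "alteration_type_tests.tsv"))
    write_table(alt$cohort_ranking, file.path(outdir, "cohort_ranking.tsv"))
    write_table(net$centrality, file.path(outdir, "centrality.tsv"))
    write_table(prog$results, file.path(outdir, "prognosis.tsv"))
    write_table(hm$distances, file.path(outdir, "hallmark_distances.tsv"))
    write_table(hm$summary, file.path(outdir, "phenotype_summary.tsv"))
    write_table(as.data.frame(scores), file.path(outdir, "score_matrix.tsv"))
    writeLines(ess, file.path(outdir, "essential_genes.txt"))
    write_table(surv$table, file.path(outdir, "os_comparison.tsv"))
    write_table(tally, file.path(outdir, "report.tsv"))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}
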