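#' Rank-normalize values to CR-cancer scores in \[0, 1\]
#'
#' With N ranked genes and average-rank tie handling, the score is
#' `(N - rank) / (N - 1)`: the best-ranked gene scores 1, the worst 0,
#' and tied genes share a score. `direction = "lower_better"` reverses the
#' ordering before ranking. NA values are excluded from ranking and stay
#' NA. A single ranked gene scores 1; when all values are identical every
#' gene scores 0.5 (with a warning).
#'
#' @param values Named numeric vector (gene -> layer value).
#' @param direction `"higher_better"` or `"lower_better"`.
#' @return Named numeric vector of scores in \[0, 1\] (NA preserved).
#' @export
rank_to_score <- function(values, direction = c("higher_better",
                                                "lower_better")) {
  direction <- match.arg(direction)
  stopifnot(!is.null(names(values)), length(values) >= 1)
  out <- rep(NA_real_, length(values))
  names(out) <- names(values)
  ok <- !is.na(values)
  v <- values[ok]
  n <- length(v)
  if (n == 0) return(out)
  if (n == 1) {
    out[ok] <- 1
    return(out)
  }
  if (length(unique(v)) == 1L) {
    warning("all values identical; every score set to 0.5")
    out[ok] <- 0.5
    return(out)
  }
  key <- if (direction == "higher_better") -v else v
  r <- rank(key, ties.method = "average")
  out[ok] <- (n - r) / (n - 1)
  out
}

#' Ranking direction of each evidence layer
#'
#' Alteration: higher mean alteration frequency is better. Network: higher
#' degree centrality is better. Prognosis: a smaller minimum log-rank p
#' among unfavorable-direction results is better. Hallmark: a smaller
#' minimum distance to any hallmark phenotype is better.
#'
#' @return Named character vector over the four layers.
#' @export
layer_directions <- function() {
  c(alteration = "higher_better", network = "higher_better",
    prognosis = "lower_better", hallmark = "lower_better")
}

#' Assemble per-layer CR-cancer scores for a gene universe
#'
#' Applies [rank_to_score()] per layer with the directions of
#' [layer_directions()]. Genes missing from a layer get NA in that layer.
#'
#' @param genes Character vector: the gene universe.
#' @param alteration Named numeric, gene -> mean alteration frequency.
#' @param network Named numeric, gene -> degree centrality.
#' @param prognosis Named numeric, gene -> minimum unfavorable log-rank p.
#' @param hallmark Named numeric, gene -> minimum phenotype distance.
#' @return data.frame (class `score_matrix`) with gene and one score
#'   column per layer.
#' @export
build_score_matrix <- function(genes, alteration = NULL, network = NULL,
                               prognosis = NULL, hallmark = NULL) {
  genes <- sort(unique(genes))
  layers <- list(alteration = alteration, network = network,
                 prognosis = prognosis, hallmark = hallmark)
  dirs <- layer_directions()
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (nm in names(layers)) {
    v <- rep(NA_real_, length(genes))
    names(v) <- genes
    lay <- layers[[nm]]
    if (!is.null(lay)) {
      common <- intersect(names(lay), genes)
      v[common] <- lay[common]
      v <- suppressWarnings(rank_to_score(v, dirs[[nm]]))
    }
    out[[nm]] <- unname(v)
  }
  class(out) <- c("score_matrix", "data.frame")
  out
}

#' Integrate layer scores and flag essential genes
#'
#' Layer scores are combined per gene (arithmetic mean over non-NA layers
#' by default; zero-filling of missing layers and a min combiner are
#' available). Under the default `"rank_then_cut"` policy the combined
#' values are passed through a final rank-to-score step so that the strict
#' `> 0.9` cutoff coincides with the top 10% of genes; `"raw_mean"` applies
#' the cutoff to the combined value directly.
#'
#' @param scores A `score_matrix` from [build_score_matrix()].
#' @param policy `"rank_then_cut"` (default) or `"raw_mean"`.
#' @param combine `"mean"` (default) or `"min"` over layer scores.
#' @param missing `"exclude"` (default; NA layers dropped from the
#'   combiner) or `"zero"` (NA treated as 0).
#' @param cutoff Essentiality cutoff on the integrated score (default 0.9,
#'   strict).
#' @return The score matrix with `integrated_score` and `essential_flag`
#'   columns added; genes NA in every layer get NA and FALSE.
#' @export
integrate_scores <- function(scores,
                             policy = c("rank_then_cut", "raw_mean"),
                             combine = c("mean", "min"),
                             missing = c("exclude", "zero"),
                             cutoff = 0.9) {
  policy <- match.arg(policy)
  combine <- match.arg(combine)
  missing <- match.arg(missing)
  stopifnot(inherits(scores, "score_matrix"))
  layer_cols <- intersect(names(layer_directions()), names(scores))
  mat <- as.matrix(scores[layer_cols])
  if (missing == "zero") mat[is.na(mat)] <- 0
  comb_fun <- if (combine == "mean") {
    function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  } else {
    function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)
  }
  combined <- apply(mat, 1, comb_fun)
  names(combined) <- scores$gene
  integrated <- if (policy == "rank_then_cut") {
    suppressWarnings(rank_to_score(combined, "higher_better"))
  } else {
    combined
  }
  scores$integrated_score <- unname(integrated)
  scores$essential_flag <- !is.na(integrated) & integrated > cutoff
  attr(scores, "policy") <- policy
  attr(scores, "combine") <- combine
  attr(scores, "missing") <- missing
  attr(scores, "cutoff") <- cutoff
  scores
}

#' Essential genes of an integrated score matrix
#'
#' @param scores Output of [integrate_scores()].
#' @return Character vector of genes with `essential_flag`.
#' @export
essential_genes <- function(scores) {
  stopifnot(is.data.frame(scores), "essential_flag" %in% names(scores))
  sort(scores$gene[scores$essential_flag])
}
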