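#' Shortest directed distances from proteins to hallmark phenotypes
#'
#' Distance = minimum number of directed edges from a protein to a
#' phenotype sink; edge signs are carried in the input but ignored for
#' traversal (positive and negative regulations count alike). Computed by
#' breadth-first search backwards from each phenotype over the reversed
#' graph. Proteins absent from the graph are unreachable (with a warning).
#' A protein directly wired to a phenotype has distance 1; distances are
#' never 0 because proteins and phenotypes are disjoint node sets.
#'
#' @param edges Directed edge data.frame with source, target (sign
#'   optional). Phenotypes must not appear as sources.
#' @param proteins Character vector of proteins to score.
#' @param phenotypes Phenotype vocabulary (default
#'   `hallmark_phenotypes("results")`).
#' @return data.frame with protein, phenotype, distance (NA when
#'   unreachable).
#' @export
shortest_distances <- function(edges, proteins,
                               phenotypes = hallmark_phenotypes("results")) {
  stopifnot(all(c("source", "target") %in% names(edges)))
  if (any(edges$source %in% phenotypes)) {
    stop("phenotypes must be sink nodes (no outgoing edges)", call. = FALSE)
  }
  nodes <- unique(c(edges$source, edges$target, phenotypes))
  missing <- setdiff(proteins, c(edges$source, edges$target))
  if (length(missing) > 0) {
    warning(length(missing), " protein(s) absent from the graph; unreachable")
  }
  id <- stats::setNames(seq_along(nodes), nodes)
  ## reversed adjacency: for BFS from a phenotype towards sources
  radj <- split(id[edges$source], id[edges$target])
  dist_from <- function(phen) {
    d <- rep(NA_integer_, length(nodes))
    frontier <- id[[phen]]
    level <- 0L
    d[frontier] <- 0L
    while (length(frontier) > 0) {
      level <- level + 1L
      nxt <- unique(unlist(radj[as.character(frontier)], use.names = FALSE))
      nxt <- nxt[is.na(d[nxt])]
      d[nxt] <- level
      frontier <- nxt
    }
    d
  }
  out <- lapply(phenotypes, function(ph) {
    d <- dist_from(ph)
    dist <- d[id[proteins]]
    dist[!is.na(dist) & dist == 0L] <- NA_integer_  # protein == phenotype never
    data.frame(protein = proteins, phenotype = ph, distance = dist,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-phenotype mean distance and reachable-protein count
#'
#' Unreachable proteins are excluded from the mean; `n_proteins` counts
#' only reachable ones.
#'
#' @param records Output of [shortest_distances()].
#' @return data.frame with phenotype, mean_distance, n_proteins.
#' @export
phenotype_summary <- function(records) {
  stopifnot(all(c("protein", "phenotype", "distance") %in% names(records)))
  phen <- unique(records$phenotype)
  rows <- lapply(phen, function(ph) {
    d <- records$distance[records$phenotype == ph]
    d <- d[!is.na(d)]
    data.frame(phenotype = ph,
               mean_distance = if (length(d) > 0) mean(d) else NA_real_,
               n_proteins = length(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise phenotype distance comparisons with Bonferroni correction
#'
#' Every unordered pair of phenotypes with at least two reachable proteins
#' each is compared by the Mann-Whitney U test on reachable distances;
#' significance is declared at `alpha / m` where m is the number of pairs.
#'
#' @param records Output of [shortest_distances()].
#' @param alpha Family-wise level (default 0.001).
#' @return data.frame with phenotype_a, phenotype_b, statistic, p_value,
#'   n1, n2, alpha_adjusted, significant.
#' @export
compare_phenotypes <- function(records, alpha = 0.001) {
  phen <- sort(unique(records$phenotype))
  dists <- lapply(phen, function(ph) {
    d <- records$distance[records$phenotype == ph]
    d[!is.na(d)]
  })
  names(dists) <- phen
  usable <- phen[vapply(dists, length, integer(1)) >= 2]
  if (length(usable) < 2) {
    stop("need at least 2 phenotypes with at least 2 reachable proteins",
         call. = FALSE)
  }
  pairs <- utils::combn(usable, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    tst <- suppressWarnings(mann_whitney_u(dists[[a]], dists[[b]]))
    data.frame(phenotype_a = a, phenotype_b = b, statistic = tst$statistic,
               p_value = tst$p_value, n1 = tst$n1, n2 = tst$n2,
               alpha_adjusted = alpha / m,
               significant = tst$p_value < alpha / m,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full hallmark layer
#'
#' Shortest distances for every protein, per-phenotype summary, and the
#' Bonferroni-corrected pairwise comparison, plus each protein's minimum
#' distance over phenotypes (the per-gene value used by the scoring
#' layer).
#'
#' @param edges Directed causal edge list.
#' @param proteins Proteins to score.
#' @param phenotypes Phenotype vocabulary.
#' @param alpha Family-wise level for the pairwise comparison.
#' @return List with `distances`, `summary`, `tests` (NULL when fewer
#'   than two phenotypes are usable), `min_distance` (named numeric).
#' @export
hallmark_layer <- function(edges, proteins,
                           phenotypes = hallmark_phenotypes("results"),
                           alpha = 0.001) {
  dist <- suppressWarnings(shortest_distances(edges, proteins, phenotypes))
  tests <- tryCatch(compare_phenotypes(dist, alpha = alpha),
                    error = function(e) NULL)
  mind <- tapply(dist$distance, dist$protein,
                 function(d) if (all(is.na(d))) NA_real_
                             else min(d, na.rm = TRUE))
  list(distances = dist,
       summary = phenotype_summary(dist),
       tests = tests,
       min_distance = stats::setNames(as.numeric(mind), names(mind)))
}
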