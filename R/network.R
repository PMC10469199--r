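#' Filter an interactome to high-confidence edges
#'
#' Self-loops are dropped with a warning, duplicate undirected pairs are
#' collapsed keeping the maximum confidence, and only edges with
#' confidence strictly greater than the cutoff are retained.
#'
#' @param edges data.frame with protein_a, protein_b, confidence.
#' @param cutoff Confidence cutoff in \[0, 1\] (default 0.9; strict `>`).
#' @return Filtered edge data.frame with canonicalized pair order.
#' @export
filter_edges <- function(edges, cutoff = 0.9) {
  stopifnot(all(c("protein_a", "protein_b", "confidence") %in% names(edges)),
            cutoff >= 0, cutoff <= 1)
  loops <- edges$protein_a == edges$protein_b
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    edges <- edges[!loops, , drop = FALSE]
  }
  if (nrow(edges) > 0) {
    a <- pmin(edges$protein_a, edges$protein_b)
    b <- pmax(edges$protein_a, edges$protein_b)
    edges$protein_a <- a
    edges$protein_b <- b
    edges <- edges[order(edges$protein_a, edges$protein_b,
                         -edges$confidence), , drop = FALSE]
    edges <- edges[!duplicated(edges[c("protein_a", "protein_b")]), ,
                   drop = FALSE]
  }
  edges <- edges[edges$confidence > cutoff, , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Extract the CR-driver interactome subnetwork
#'
#' From an already-filtered edge list, retains exactly the CR proteins
#' with at least one edge to a cancer driver protein, plus the driver
#' proteins with at least one edge to a retained CR protein, and the edges
#' induced by the retained node set. The operation is idempotent.
#'
#' @param edges Filtered edge data.frame (see [filter_edges()]).
#' @param annotations CR gene annotation data.frame (gene, category,
#'   is_cancer_driver).
#' @param drivers Character vector of cancer driver protein symbols
#'   (may overlap the CR set; defaults to the annotation driver flags).
#' @return List with `nodes` (node, category, is_cr, is_driver) and
#'   `edges`.
#' @export
extract_cr_network <- function(edges, annotations, drivers = NULL) {
  cr <- annotations$gene
  if (is.null(drivers)) {
    drivers <- annotations$gene[annotations$is_cancer_driver]
  } else {
    drivers <- union(drivers,
                     annotations$gene[annotations$is_cancer_driver])
  }
  to_driver <- (edges$protein_a %in% drivers) | (edges$protein_b %in% drivers)
  cr_keep <- sort(unique(c(
    edges$protein_a[to_driver & edges$protein_a %in% cr &
                      edges$protein_b %in% drivers],
    edges$protein_b[to_driver & edges$protein_b %in% cr &
                      edges$protein_a %in% drivers]
  )))
  drv_keep <- sort(unique(c(
    edges$protein_a[edges$protein_a %in% drivers &
                      edges$protein_b %in% cr_keep],
    edges$protein_b[edges$protein_b %in% drivers &
                      edges$protein_a %in% cr_keep]
  )))
  nodes <- sort(unique(c(cr_keep, drv_keep)))
  kept <- edges[edges$protein_a %in% nodes & edges$protein_b %in% nodes, ,
                drop = FALSE]
  rownames(kept) <- NULL
  cat_of <- stats::setNames(annotations$category, annotations$gene)
  node_df <- data.frame(
    node = nodes,
    category = ifelse(nodes %in% cr, unname(cat_of[nodes]), "driver"),
    is_cr = nodes %in% cr,
    is_driver = nodes %in% drivers,
    stringsAsFactors = FALSE
  )
  list(nodes = node_df, edges = kept)
}

#' Degree centrality of every node
#'
#' Degree = number of retained edges incident to the node; isolated nodes
#' get 0. The handshake identity (sum of degrees = 2 x edge count) is
#' asserted on every call.
#'
#' @param nodes Character vector of node symbols, or the `nodes` element
#'   of [extract_cr_network()].
#' @param edges Edge data.frame within the node set.
#' @return data.frame with node, degree (plus category / flags when a node
#'   table was supplied).
#' @export
degree_centrality <- function(nodes, edges) {
  node_df <- NULL
  if (is.data.frame(nodes)) {
    node_df <- nodes
    nodes <- nodes$node
  }
  stopifnot(all(edges$protein_a %in% nodes),
            all(edges$protein_b %in% nodes))
  deg <- table(factor(c(edges$protein_a, edges$protein_b), levels = nodes))
  stopifnot(sum(deg) == 2 * nrow(edges))  # handshake lemma
  out <- data.frame(node = nodes, degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  if (!is.null(node_df)) {
    out <- merge(node_df, out, by = "node", sort = TRUE)
  }
  out[order(out$node), , drop = FALSE]
}

#' Mean degree per category and driver-vs-CR comparison
#'
#' Arithmetic mean degree for each CR category and for the (possibly
#' overlapping) driver group, plus a Mann-Whitney U comparison of driver
#' degrees against the pooled CR degrees. Categories overlap: a CR protein
#' that is also a driver contributes to both its CR category and the
#' driver group.
#'
#' @param centrality Output of [degree_centrality()] on an extracted
#'   network (must carry `category`, `is_cr`, `is_driver`).
#' @return List with `means` (data.frame group, n, mean_degree) and
#'   `test` (a `cr_test`, or NULL when a group is empty).
#' @export
group_mean_degree <- function(centrality) {
  stopifnot(all(c("degree", "category", "is_cr", "is_driver")
                %in% names(centrality)))
  groups <- c(gene_categories(), "driver")
  means <- lapply(groups, function(g) {
    deg <- if (g == "driver") {
      centrality$degree[centrality$is_driver]
    } else {
      centrality$degree[centrality$is_cr & centrality$category == g]
    }
    data.frame(group = g, n = length(deg),
               mean_degree = if (length(deg) > 0) mean(deg) else NA_real_,
               stringsAsFactors = FALSE)
  })
  means <- do.call(rbind, means)
  drv <- centrality$degree[centrality$is_driver]
  crd <- centrality$degree[centrality$is_cr]
  test <- if (length(drv) > 0 && length(crd) > 0) {
    suppressWarnings(mann_whitney_u(drv, crd))
  } else NULL
  list(means = means, test = test)
}

#' Run the full network layer
#'
#' Filters the interactome at the confidence cutoff, extracts the
#' CR-driver subnetwork, and computes degree centrality with group means.
#'
#' @param edges Raw weighted edge list.
#' @param annotations CR gene annotations.
#' @param drivers Additional driver protein symbols.
#' @param cutoff Confidence cutoff (default 0.9, strict).
#' @return List with `network`, `centrality`, `group_means`.
#' @export
network_layer <- function(edges, annotations, drivers = NULL, cutoff = 0.9) {
  kept <- filter_edges(edges, cutoff)
  net <- extract_cr_network(kept, annotations, drivers)
  centrality <- degree_centrality(net$nodes, net$edges)
  list(network = net,
       centrality = centrality,
       group_means = group_mean_degree(centrality))
}
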