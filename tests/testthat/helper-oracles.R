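# Independent oracles and fixture builders shared across the suite.
# These re-derive expected values by brute force or via reference
# implementations (survival, igraph, stats::wilcox.test) and must stay
# independent of the package's own code paths.

# Brute-force two-sided Mann-Whitney p by permutation of group labels,
# written directly from the definition (no shared code with the package).
oracle_mw_exact_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * (n - n1) / 2
  sets <- utils::combn(n, n1)
  u_all <- apply(sets, 2, u_of)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Floyd-Warshall all-pairs shortest hop counts on a directed edge list.
oracle_floyd_warshall <- function(edges, nodes) {
  m <- length(nodes)
  D <- matrix(Inf, m, m, dimnames = list(nodes, nodes))
  diag(D) <- 0
  D[cbind(match(edges$source, nodes), match(edges$target, nodes))] <- 1
  for (k in seq_len(m)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

# Random directed graph over p proteins and the given phenotype sinks.
random_causal_graph <- function(n_proteins, phenotypes, density, seed) {
  set.seed(seed)
  proteins <- sprintf("P%02d", seq_len(n_proteins))
  pairs <- expand.grid(source = proteins,
                       target = c(proteins, phenotypes),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  keep <- runif(nrow(pairs)) < density
  edges <- pairs[keep, ]
  edges$sign <- sample(c(-1L, 1L), nrow(edges), replace = TRUE)
  rownames(edges) <- NULL
  list(proteins = proteins, edges = edges)
}

# Random undirected weighted edge list over the given node symbols.
random_ppi <- function(nodes, n_edges, seed, conf_min = 0, conf_max = 1) {
  set.seed(seed)
  all_pairs <- t(utils::combn(nodes, 2))
  idx <- sample.int(nrow(all_pairs), n_edges)
  data.frame(protein_a = all_pairs[idx, 1], protein_b = all_pairs[idx, 2],
             confidence = runif(n_edges, conf_min, conf_max),
             stringsAsFactors = FALSE)
}

# Small annotation table with the given per-category gene counts.
make_annotations <- function(n_ccc = 2, n_ccg = 3, n_nmcre = 5,
                             driver_every = 3) {
  n <- n_ccc + n_ccg + n_nmcre
  data.frame(
    gene = sprintf("G%03d", seq_len(n)),
    category = rep(c("CCC", "CCG", "NMCRE"), times = c(n_ccc, n_ccg, n_nmcre)),
    is_cancer_driver = seq_len(n) %% driver_every == 0,
    stringsAsFactors = FALSE
  )
}

# Tiny sim config for fast generator tests.
tiny_config <- function(seed = 1, ...) {
  genes <- make_annotations(1, 2, 3)
  sim_config(
    seed = seed,
    cohorts = data.frame(cancer_type = c("AA", "BB"),
                         n_patients = c(10L, 20L),
                         stringsAsFactors = FALSE),
    genes = genes,
    driver_proteins = c("DRVA", "DRVB"),
    ...
  )
}

write_tsv_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
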