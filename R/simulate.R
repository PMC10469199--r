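#' Hallmark phenotype vocabularies
#'
#' Two nine-phenotype presets are in circulation for hallmark sink nodes of
#' causal cancer networks; both ship here. The `"results"` preset (the
#' default throughout the package) names genome instability and deregulated
#' cellular energetics; the `"methods"` preset names DNA repair and
#' glycolysis instead.
#'
#' @param preset `"results"` or `"methods"`.
#' @return Character vector of nine phenotype names.
#' @export
hallmark_phenotypes <- function(preset = c("results", "methods")) {
  preset <- match.arg(preset)
  common <- c("proliferation", "resisting_cell_death", "metastasis",
              "angiogenesis", "inflammation", "immortality",
              "differentiation")
  if (preset == "results") {
    c(common, "energetics", "genome_instability")
  } else {
    c(common, "dna_repair", "glycolysis")
  }
}

## internal: deterministic per-generator sub-stream seed.
## Polynomial hash of the generator name folded into the global seed, so
## adding a generator never perturbs the draws of another.
substream_seed <- function(seed, name) {
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(name)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

## internal: draw n confidences from a named law on [0,1]
draw_confidence <- function(law, n) {
  x <- switch(law$name,
    uniform = stats::runif(n, law$min, law$max),
    beta    = stats::rbeta(n, law$shape1, law$shape2),
    point   = rep(law$value, n),
    stop("unknown confidence law: ", law$name, call. = FALSE)
  )
  pmin(pmax(x, 0), 1)
}

#' Build a simulation configuration
#'
#' Bundles and validates every parameter of the synthetic-data generators.
#' One global `seed` fixes all randomness; each generator derives its own
#' sub-stream seed from it deterministically.
#'
#' @param seed Integer; master seed for all generators.
#' @param cohorts data.frame with `cancer_type`, `n_patients`.
#' @param genes data.frame with `gene`, `category`, `is_cancer_driver`
#'   (the CR gene annotation table the generators emulate).
#' @param driver_proteins Character vector of additional (non-CR) cancer
#'   driver protein symbols included in the interactome and causal graph.
#' @param base_rates Named numeric, per-alteration-type Bernoulli rate per
#'   patient-gene.
#' @param planted_alteration_genes Named numeric, gene -> rate multiplier
#'   (> 0) applied on top of every base rate.
#' @param ppi_n_edges Number of distinct undirected interactome edges.
#' @param ppi_confidence_law List describing the confidence distribution:
#'   `list(name = "uniform", min, max)`, `list(name = "beta", shape1,
#'   shape2)` or `list(name = "point", value)`.
#' @param hub_genes Named integer, gene -> number of guaranteed
#'   high-confidence (> 0.95) edges to driver proteins; the planted-hub
#'   mechanism for the network layer.
#' @param causal_density Probability of each directed protein -> protein
#'   and protein -> phenotype causal edge.
#' @param phenotype_link_genes Genes wired directly (distance 1) to every
#'   hallmark phenotype; the planted-proximity mechanism for the hallmark
#'   layer.
#' @param phenotypes Phenotype vocabulary (see [hallmark_phenotypes()]).
#' @param hazard_effects Named numeric, gene -> log hazard ratio per
#'   standard deviation of expression in the prognosis-layer cohorts.
#' @param baseline_hazard Baseline exponential hazard (per month); the
#'   default `log(2)/55` gives a 55-month baseline median survival.
#' @param altered_log_hr Log hazard ratio of the altered group in the
#'   metastatic overall-survival cohort; the default `log(55/30)` gives
#'   group medians of 30 vs 55 months.
#' @param altered_fraction Fraction of altered patients in the metastatic
#'   cohort (default 0.59).
#' @param censor_rate Target censoring fraction in \[0, 1); independent
#'   exponential censoring is calibrated against the baseline hazard.
#' @param n_survival Patients per simulated survival cohort.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       cohorts,
                       genes,
                       driver_proteins = character(0),
                       base_rates = default_base_rates(),
                       planted_alteration_genes = numeric(0),
                       ppi_n_edges = 0L,
                       ppi_confidence_law = list(name = "uniform",
                                                 min = 0.15, max = 1),
                       hub_genes = integer(0),
                       causal_density = 0,
                       phenotype_link_genes = character(0),
                       phenotypes = hallmark_phenotypes("results"),
                       hazard_effects = numeric(0),
                       baseline_hazard = log(2) / 55,
                       altered_log_hr = log(55 / 30),
                       altered_fraction = 0.59,
                       censor_rate = 0.3,
                       n_survival = 500L) {
  stopifnot(is.data.frame(cohorts),
            all(c("cancer_type", "n_patients") %in% names(cohorts)),
            all(cohorts$n_patients >= 1),
            is.data.frame(genes),
            all(c("gene", "category", "is_cancer_driver") %in% names(genes)),
            all(genes$category %in% gene_categories()))
  if (any(base_rates < 0 | base_rates > 1)) {
    stop("base_rates must lie in [0, 1]", call. = FALSE)
  }
  if (length(setdiff(names(base_rates), alteration_types())) > 0) {
    stop("base_rates names must be alteration types", call. = FALSE)
  }
  if (any(planted_alteration_genes <= 0)) {
    stop("rate multipliers must be > 0", call. = FALSE)
  }
  if (censor_rate < 0 || censor_rate >= 1) {
    stop("censor_rate must lie in [0, 1)", call. = FALSE)
  }
  if (altered_fraction < 0 || altered_fraction > 1) {
    stop("altered_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (causal_density < 0 || causal_density > 1) {
    stop("causal_density must lie in [0, 1]", call. = FALSE)
  }
  cfg <- list(seed = as.integer(seed), cohorts = cohorts, genes = genes,
              driver_proteins = driver_proteins, base_rates = base_rates,
              planted_alteration_genes = planted_alteration_genes,
              ppi_n_edges = as.integer(ppi_n_edges),
              ppi_confidence_law = ppi_confidence_law,
              hub_genes = hub_genes, causal_density = causal_density,
              phenotype_link_genes = phenotype_link_genes,
              phenotypes = phenotypes, hazard_effects = hazard_effects,
              baseline_hazard = baseline_hazard,
              altered_log_hr = altered_log_hr,
              altered_fraction = altered_fraction,
              censor_rate = censor_rate,
              n_survival = as.integer(n_survival))
  class(cfg) <- "sim_config"
  cfg
}

#' Per-type alteration base rates used by default
#'
#' Mean per-patient-gene alteration frequencies by type: mRNA
#' downregulation 0.028, mRNA upregulation 0.019, CNV amplification 0.009,
#' CNV deep deletion 0.003, driver mutation 0.0026, fusion 0.0003.
#'
#' @return Named numeric vector over the six alteration types.
#' @export
default_base_rates <- function() {
  c(mrna_down = 0.028, mrna_up = 0.019, cnv_amp = 0.009,
    cnv_deepdel = 0.003, driver_mutation = 0.0026, fusion = 0.0003)
}

#' Default scaled-down study configuration
#'
#' A desk-scale stand-in for the full pan-cancer study: 40 CR genes in the
#' three categories at roughly the 17:59:130 proportions of the real gene
#' set (3 CCC, 12 CCG, 25 NMCRE, a quarter of them drivers), 30 additional
#' non-CR driver proteins, four cohorts of 500 patients, type-specific
#' alteration base rates, a 600-edge interactome with uniform confidences
#' on \[0.15, 1\], a causal graph of density 0.03 over nine hallmark
#' phenotypes, and exponential survival (baseline median 55 months, 30%
#' censoring). One gene (`CRG001`) carries the planted multi-layer signal:
#' alteration rate multiplier 30, log hazard ratio 1.1, 15 guaranteed
#' high-confidence driver interactions, and direct links to every hallmark
#' phenotype.
#'
#' @param seed Master seed.
#' @param planted If `FALSE`, all planted effects are switched off (null
#'   configuration).
#' @return A `sim_config`.
#' @export
default_sim_config <- function(seed = 1L, planted = TRUE) {
  n_cr <- 40L
  categories <- rep(c("CCC", "CCG", "NMCRE"), times = c(3L, 12L, 25L))
  genes <- data.frame(
    gene = sprintf("CRG%03d", seq_len(n_cr)),
    category = categories,
    is_cancer_driver = seq_len(n_cr) %% 4L == 0L,
    stringsAsFactors = FALSE
  )
  cohorts <- data.frame(
    cancer_type = c("BRCA", "LUAD", "KIRC", "STAD"),
    n_patients = rep(500L, 4L),
    stringsAsFactors = FALSE
  )
  drivers <- sprintf("DRV%03d", seq_len(30L))
  planted_gene <- "CRG001"
  sim_config(
    seed = seed,
    cohorts = cohorts,
    genes = genes,
    driver_proteins = drivers,
    planted_alteration_genes =
      if (planted) stats::setNames(30, planted_gene) else numeric(0),
    ppi_n_edges = 600L,
    hub_genes =
      if (planted) stats::setNames(15L, planted_gene) else integer(0),
    causal_density = 0.03,
    phenotype_link_genes = if (planted) planted_gene else character(0),
    hazard_effects =
      if (planted) stats::setNames(1.1, planted_gene) else numeric(0)
  )
}

#' Simulate per-patient alteration calls
#'
#' For every patient x gene x alteration type an independent Bernoulli
#' draw at `base_rate * multiplier` (clamped to 1 with a warning) yields
#' at most one call. Deterministic given the config seed.
#'
#' @param config A `sim_config`.
#' @return data.frame of alteration calls (patient_id, cancer_type, gene,
#'   alteration_type).
#' @export
gen_alteration_calls <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "alteration_calls"))
  genes <- config$genes$gene
  mult <- rep(1, length(genes))
  names(mult) <- genes
  planted <- intersect(names(config$planted_alteration_genes), genes)
  mult[planted] <- config$planted_alteration_genes[planted]
  types <- intersect(alteration_types(), names(config$base_rates))
  out <- vector("list", nrow(config$cohorts) * length(types))
  k <- 0L
  clamped <- FALSE
  for (i in seq_len(nrow(config$cohorts))) {
    code <- config$cohorts$cancer_type[i]
    n <- config$cohorts$n_patients[i]
    patients <- sprintf("%s_P%04d", code, seq_len(n))
    for (t in types) {
      p <- config$base_rates[[t]] * mult
      if (any(p > 1)) clamped <- TRUE
      p <- pmin(p, 1)
      u <- stats::runif(n * length(genes))
      hit <- which(u < rep(p, each = n))
      k <- k + 1L
      if (length(hit) > 0) {
        out[[k]] <- data.frame(
          patient_id = patients[(hit - 1L) %% n + 1L],
          cancer_type = code,
          gene = genes[(hit - 1L) %/% n + 1L],
          alteration_type = t,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (clamped) warning("some rate x multiplier products exceeded 1; clamped")
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(data.frame(patient_id = character(0), cancer_type = character(0),
                      gene = character(0), alteration_type = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a weighted protein-protein edge list
#'
#' Samples `ppi_n_edges` distinct undirected pairs (no self-loops) over the
#' CR genes plus driver proteins, with confidences from the configured law.
#' Hub genes additionally receive guaranteed high-confidence (> 0.95)
#' edges to randomly chosen driver proteins. Duplicate pairs keep the
#' maximum confidence. Deterministic given the config seed.
#'
#' @param config A `sim_config`.
#' @return data.frame of edges (protein_a, protein_b, confidence).
#' @export
gen_ppi_edges <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "ppi_edges"))
  nodes <- c(config$genes$gene, config$driver_proteins)
  m <- length(nodes)
  if (m < 2) stop("need at least 2 proteins", call. = FALSE)
  n_pairs <- m * (m - 1) / 2
  if (config$ppi_n_edges > n_pairs) {
    stop("ppi_n_edges exceeds the number of distinct pairs (", n_pairs, ")",
         call. = FALSE)
  }
  empty <- data.frame(protein_a = character(0), protein_b = character(0),
                      confidence = numeric(0), stringsAsFactors = FALSE)
  edges <- empty
  if (config$ppi_n_edges > 0) {
    idx <- sort(sample.int(n_pairs, config$ppi_n_edges))
    ut <- which(upper.tri(matrix(0L, m, m)), arr.ind = TRUE)
    a <- ut[idx, 1L]
    b <- ut[idx, 2L]
    edges <- data.frame(protein_a = nodes[a], protein_b = nodes[b],
                        confidence = draw_confidence(config$ppi_confidence_law,
                                                     length(idx)),
                        stringsAsFactors = FALSE)
  }
  hubs <- intersect(names(config$hub_genes), config$genes$gene)
  drivers <- config$driver_proteins
  if (length(hubs) > 0 && length(drivers) > 0) {
    extra <- lapply(hubs, function(g) {
      k <- min(config$hub_genes[[g]], length(drivers))
      partners <- sample(drivers, k)
      data.frame(protein_a = g, protein_b = partners,
                 confidence = stats::runif(k, 0.951, 1),
                 stringsAsFactors = FALSE)
    })
    edges <- rbind(edges, do.call(rbind, extra))
  }
  if (nrow(edges) == 0) return(empty)
  ## canonical order + keep max confidence over duplicate pairs
  key_a <- pmin(edges$protein_a, edges$protein_b)
  key_b <- pmax(edges$protein_a, edges$protein_b)
  edges$protein_a <- key_a
  edges$protein_b <- key_b
  edges <- edges[order(edges$protein_a, edges$protein_b, -edges$confidence), ]
  edges <- edges[!duplicated(edges[c("protein_a", "protein_b")]), ]
  rownames(edges) <- NULL
  edges
}

#' Simulate a signed directed causal graph with phenotype sinks
#'
#' Each ordered protein pair and each protein -> phenotype pair is wired
#' independently with probability `causal_density`; edges carry a random
#' sign. Phenotype-linked genes additionally get a direct positive edge to
#' every phenotype. Phenotypes are sinks (never sources). Deterministic
#' given the config seed.
#'
#' @param config A `sim_config`.
#' @return data.frame of edges (source, target, sign).
#' @export
gen_causal_graph <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "causal_graph"))
  proteins <- c(config$genes$gene, config$driver_proteins)
  phen <- config$phenotypes
  m <- length(proteins)
  d <- config$causal_density
  out <- list()
  if (d > 0 && m > 1) {
    src <- rep(seq_len(m), each = m)
    tgt <- rep(seq_len(m), times = m)
    keep <- src != tgt & stats::runif(m * m) < d
    if (any(keep)) {
      out$pp <- data.frame(source = proteins[src[keep]],
                           target = proteins[tgt[keep]],
                           stringsAsFactors = FALSE)
    }
  }
  if (d > 0 && length(phen) > 0) {
    src <- rep(seq_len(m), each = length(phen))
    tgt <- rep(seq_along(phen), times = m)
    keep <- stats::runif(m * length(phen)) < d
    if (any(keep)) {
      out$pf <- data.frame(source = proteins[src[keep]],
                           target = phen[tgt[keep]],
                           stringsAsFactors = FALSE)
    }
  }
  linked <- intersect(config$phenotype_link_genes, proteins)
  if (length(linked) > 0 && length(phen) > 0) {
    out$link <- expand.grid(source = linked, target = phen,
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(source = character(0), target = character(0),
                      sign = integer(0), stringsAsFactors = FALSE))
  }
  edges <- do.call(rbind, out)
  edges$sign <- ifelse(stats::runif(nrow(edges)) < 0.5, -1L, 1L)
  if (!is.null(out$link)) {
    edges$sign[seq.int(nrow(edges) - nrow(out$link) + 1L, nrow(edges))] <- 1L
  }
  edges <- edges[!duplicated(edges[c("source", "target")]), ]
  edges <- edges[order(edges$source, edges$target), ]
  rownames(edges) <- NULL
  edges
}

#' Simulate a survival cohort under exponential proportional hazards
#'
#' Event times are exponential with hazard `h0 * exp(beta * z)` where `z`
#' is a standardized expression value (`mode = "expression"`) or an altered
#' indicator (`mode = "altered"`). Censoring is independent exponential,
#' calibrated so that a fraction `censor_rate` of baseline-hazard patients
#' is censored (`censor_rate = 0` means every record is an observed
#' event). Deterministic given the config seed, mode and gene.
#'
#' @param config A `sim_config`.
#' @param mode `"expression"` or `"altered"`.
#' @param gene Gene symbol; in expression mode selects the planted log
#'   hazard ratio from `config$hazard_effects` (0 when absent) and the
#'   random sub-stream.
#' @param beta Log hazard ratio override.
#' @param n Cohort size; defaults to `config$n_survival` in expression
#'   mode and the total cohort size in altered mode.
#' @param altered Optional logical vector of altered indicators (altered
#'   mode); defaults to Bernoulli draws at `config$altered_fraction`.
#' @return data.frame with patient_id, time (months), event, and the
#'   covariate column (`expression` or `altered`).
#' @export
gen_survival_cohort <- function(config, mode = c("expression", "altered"),
                                gene = NULL, beta = NULL, n = NULL,
                                altered = NULL) {
  stopifnot(inherits(config, "sim_config"))
  mode <- match.arg(mode)
  if (config$censor_rate < 0) stop("censor_rate must be >= 0", call. = FALSE)
  stream <- paste0("survival_", mode, "_",
                   if (is.null(gene)) "" else gene)
  set.seed(substream_seed(config$seed, stream))
  h0 <- config$baseline_hazard
  if (mode == "expression") {
    if (is.null(n)) n <- config$n_survival
    if (is.null(beta)) {
      beta <- if (!is.null(gene) && gene %in% names(config$hazard_effects)) {
        config$hazard_effects[[gene]]
      } else 0
    }
    z <- stats::rnorm(n)
    covariate <- z
    cov_name <- "expression"
  } else {
    if (is.null(altered)) {
      if (is.null(n)) n <- sum(config$cohorts$n_patients)
      altered <- stats::runif(n) < config$altered_fraction
    } else {
      altered <- as.logical(altered)
      n <- length(altered)
    }
    if (is.null(beta)) beta <- config$altered_log_hr
    z <- as.numeric(altered)
    covariate <- altered
    cov_name <- "altered"
  }
  times <- stats::rexp(n, rate = h0 * exp(beta * z))
  event <- rep(TRUE, n)
  if (config$censor_rate > 0) {
    cens_rate <- h0 * config$censor_rate / (1 - config$censor_rate)
    ctimes <- stats::rexp(n, rate = cens_rate)
    event <- times <= ctimes
    times <- pmin(times, ctimes)
  }
  out <- data.frame(patient_id = sprintf("SP%05d", seq_len(n)),
                    time = times, event = event,
                    stringsAsFactors = FALSE)
  out[[cov_name]] <- covariate
  out
}

#' Write every synthetic input table plus a run manifest
#'
#' Generates alteration calls, cohort sizes, gene annotations, the
#' weighted interactome, the causal graph, one expression-survival cohort
#' per gene (long format) and the metastatic overall-survival cohort, and
#' writes them as tab-delimited tables together with `manifest.json`
#' recording the resolved configuration.
#'
#' @param config A `sim_config`.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
simulate_inputs <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  w <- function(df, name) {
    p <- file.path(outdir, name)
    write_table(df, p)
    p
  }
  paths$calls <- w(gen_alteration_calls(config), "alteration_calls.tsv")
  paths$cohorts <- w(config$cohorts, "cohorts.tsv")
  paths$annotations <- w(config$genes, "annotations.tsv")
  paths$ppi_edges <- w(gen_ppi_edges(config), "ppi_edges.tsv")
  paths$causal_edges <- w(gen_causal_graph(config), "causal_edges.tsv")
  expr <- lapply(config$genes$gene, function(g) {
    df <- gen_survival_cohort(config, "expression", gene = g)
    cbind(gene = g, df, stringsAsFactors = FALSE)
  })
  paths$expression_survival <- w(do.call(rbind, expr),
                                 "expression_survival.tsv")
  paths$os_survival <- w(gen_survival_cohort(config, "altered"),
                         "os_survival.tsv")
  manifest <- config
  class(manifest) <- NULL
  manifest$tool_version <-
    as.character(utils::packageVersion("chronoprio"))
  paths$manifest <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
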