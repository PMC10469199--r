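test_that("same config yields identical outputs; sub-streams are isolated", {
  cfg <- tiny_config(seed = 5, ppi_n_edges = 10L, causal_density = 0.2)
  expect_identical(gen_alteration_calls(cfg), gen_alteration_calls(cfg))
  expect_identical(gen_ppi_edges(cfg), gen_ppi_edges(cfg))
  expect_identical(gen_causal_graph(cfg), gen_causal_graph(cfg))
  expect_identical(gen_survival_cohort(cfg, "altered"),
                   gen_survival_cohort(cfg, "altered"))
  # changing an unrelated generator's parameters leaves the others' draws
  cfg2 <- tiny_config(seed = 5, ppi_n_edges = 3L, causal_density = 0.2)
  expect_identical(gen_alteration_calls(cfg), gen_alteration_calls(cfg2))
  expect_identical(gen_causal_graph(cfg), gen_causal_graph(cfg2))
})

test_that("alteration generator honours extreme base rates", {
  cfg0 <- tiny_config(base_rates = setNames(rep(0, 6), alteration_types()))
  expect_equal(nrow(gen_alteration_calls(cfg0)), 0L)

  one <- make_annotations(1, 0, 0)
  cfg1 <- sim_config(
    seed = 2,
    cohorts = data.frame(cancer_type = "AA", n_patients = 10L),
    genes = one,
    base_rates = c(mrna_up = 1)
  )
  calls <- gen_alteration_calls(cfg1)
  expect_equal(nrow(calls), 10L)
  expect_true(all(calls$alteration_type == "mrna_up"))
  expect_equal(length(unique(calls$patient_id)), 10L)
})

test_that("empirical per-type frequency converges to the base rate", {
  rates <- c(mrna_up = 0.05, cnv_amp = 0.012)
  cfg <- sim_config(
    seed = 11,
    cohorts = data.frame(cancer_type = "AA", n_patients = 4000L),
    genes = make_annotations(1, 1, 1),
    base_rates = rates
  )
  calls <- gen_alteration_calls(cfg)
  n <- 4000 * 3  # patient x gene Bernoulli draws per type
  for (t in names(rates)) {
    p <- rates[[t]]
    emp <- sum(calls$alteration_type == t) / n
    expect_lt(abs(emp - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("rate x multiplier above 1 is clamped with a warning", {
  cfg <- tiny_config(base_rates = c(mrna_up = 0.5),
                     planted_alteration_genes = c(G001 = 30))
  expect_warning(calls <- gen_alteration_calls(cfg), "clamped")
  g <- calls[calls$gene == "G001", ]
  expect_equal(nrow(g), 30L)  # every patient in both cohorts
})

test_that("ppi generator saturates, errors on overflow, and respects the law", {
  tri <- sim_config(seed = 3,
                    cohorts = data.frame(cancer_type = "AA", n_patients = 5L),
                    genes = make_annotations(1, 1, 1),
                    ppi_n_edges = 3L)
  edges <- gen_ppi_edges(tri)
  expect_equal(nrow(edges), 3L)  # the complete triangle on 3 genes
  expect_equal(sort(unique(c(edges$protein_a, edges$protein_b))),
               c("G001", "G002", "G003"))

  over <- sim_config(seed = 3,
                     cohorts = data.frame(cancer_type = "AA", n_patients = 5L),
                     genes = make_annotations(1, 1, 1),
                     ppi_n_edges = 4L)
  expect_error(gen_ppi_edges(over), "exceeds")

  zero <- tiny_config(ppi_n_edges = 0L)
  expect_equal(nrow(gen_ppi_edges(zero)), 0L)

  low <- tiny_config(ppi_n_edges = 20L,
                     ppi_confidence_law = list(name = "uniform",
                                               min = 0.1, max = 0.85))
  filtered <- filter_edges(gen_ppi_edges(low), 0.9)
  expect_equal(nrow(filtered), 0L)
})

test_that("causal generator wires chains and sinks correctly", {
  none <- tiny_config(causal_density = 0)
  expect_equal(nrow(gen_causal_graph(none)), 0L)

  # a planted phenotype-linked gene sits at distance 1 from every phenotype
  linked <- tiny_config(causal_density = 0, phenotype_link_genes = "G002")
  g <- gen_causal_graph(linked)
  expect_true(all(g$target %in% hallmark_phenotypes("results")))
  expect_true(all(g$source == "G002"))

  dense <- tiny_config(causal_density = 1)
  g <- gen_causal_graph(dense)
  expect_false(any(g$source %in% hallmark_phenotypes("results")))
  expect_true(all(g$sign %in% c(-1L, 1L)))
  # density 1: every protein reaches every phenotype directly
  d <- shortest_distances(g, c("G001", "DRVA"))
  expect_true(all(d$distance == 1L))
})

test_that("survival generator respects censoring and the closed-form median", {
  cfg <- tiny_config(censor_rate = 0)
  rec <- gen_survival_cohort(cfg, "expression", n = 200L)
  expect_true(all(rec$event))

  # exponential with hazard ln2/30: KM median recovers 30 months at n = 2000
  cfg30 <- tiny_config(seed = 17, censor_rate = 0.2,
                       baseline_hazard = log(2) / 30)
  rec <- gen_survival_cohort(cfg30, "expression", n = 2000L, beta = 0)
  med <- km_median(km_estimate(rec$time, rec$event))
  # asymptotic se of the exponential sample median: 1 / (lambda sqrt(n))
  se <- 1 / ((log(2) / 30) * sqrt(2000))
  expect_lt(abs(med$median - 30), 3 * se)
  expect_true(med$ci_low < med$median && med$median < med$ci_high)
})

test_that("simulate_inputs writes all tables plus a manifest", {
  cfg <- tiny_config(seed = 9, ppi_n_edges = 5L, causal_density = 0.1,
                     n_survival = 30L)
  outdir <- file.path(tempdir(), "siminputs")
  paths <- simulate_inputs(cfg, outdir)
  expect_true(all(file.exists(unlist(paths))))
  manifest <- jsonlite::read_json(paths$manifest)
  expect_equal(manifest$seed, 9L)
  # the written tables re-read cleanly through the validating readers
  expect_s3_class(read_annotations(paths$annotations), "data.frame")
  expect_s3_class(read_cohorts(paths$cohorts), "data.frame")
  expect_s3_class(read_ppi_edges(paths$ppi_edges), "data.frame")
  expect_s3_class(read_causal_edges(paths$causal_edges), "data.frame")
})
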