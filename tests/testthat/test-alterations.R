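make_calls <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(patient_id = r[1], cancer_type = r[2], gene = r[3],
               alteration_type = r[4], stringsAsFactors = FALSE)
  }))
}

test_that("events are counted per alteration type per patient-gene", {
  calls <- make_calls(c("P1", "AA", "G", "mrna_up"),
                      c("P1", "AA", "G", "cnv_amp"),
                      c("P2", "AA", "G", "mrna_up"),
                      c("P3", "AA", "G", "mrna_up"))
  counts <- count_events(calls)
  expect_equal(sum(counts$n_events), 4L)  # two types in one patient = 2 events
  expect_equal(counts$n_events[counts$alteration_type == "mrna_up"], 3L)

  empty <- count_events(calls[0, ])
  expect_equal(nrow(empty), 0L)

  # conservation: totals equal the number of distinct triples, and
  # duplicated calls do not double-count
  dup <- rbind(calls, calls[1, ])
  expect_equal(sum(count_events(dup)$n_events), 4L)
})

test_that("frequency normalization divides by cohort size and zero-imputes", {
  counts <- data.frame(gene = "G1", cancer_type = "AA",
                       alteration_type = "mrna_up", n_events = 56L,
                       stringsAsFactors = FALSE)
  cohorts <- data.frame(cancer_type = c("AA", "BB", "CC", "DD"),
                        n_patients = c(512L, 100L, 100L, 100L))
  freq <- normalize_frequency(counts, cohorts, genes = c("G1", "G2"))
  expect_equal(freq$per_type$f, 56 / 512)
  # gene altered in 1 of 4 cohorts with f = 0.4 there -> mean 0.1
  counts2 <- data.frame(gene = "G1", cancer_type = "BB",
                        alteration_type = "mrna_up", n_events = 40L,
                        stringsAsFactors = FALSE)
  freq2 <- normalize_frequency(counts2, cohorts, genes = c("G1", "G2"))
  expect_equal(freq2$gene_means$mean_f_gene[freq2$gene_means$gene == "G1"],
               0.1)
  expect_equal(freq2$gene_means$mean_f_gene[freq2$gene_means$gene == "G2"],
               0)
  # unknown cohort is a hard error
  bad <- data.frame(gene = "G1", cancer_type = "ZZ",
                    alteration_type = "mrna_up", n_events = 1L)
  expect_error(normalize_frequency(bad, cohorts), "absent")
})

test_that("mean-frequency gene selection uses a strict cutoff", {
  mk_freq <- function(means) {
    genes <- names(means)
    counts <- data.frame(gene = genes, cancer_type = "AA",
                         alteration_type = "mrna_up",
                         n_events = as.integer(means * 100),
                         stringsAsFactors = FALSE)
    normalize_frequency(counts,
                        data.frame(cancer_type = "AA", n_patients = 100L),
                        genes = genes)
  }
  flat <- mk_freq(c(a = 0.1, b = 0.1, c = 0.1))
  sel <- select_altered_genes(flat)
  expect_equal(sel$cutoff, 0.1)
  expect_equal(sel$selected, character(0))  # strict >

  mix <- mk_freq(c(a = 0.02, b = 0.04, c = 0.12))
  sel <- select_altered_genes(mix)
  expect_equal(sel$cutoff, 0.06)
  expect_equal(sel$selected, "c")

  # invariant to gene input order
  mix2 <- mk_freq(c(c = 0.12, a = 0.02, b = 0.04))
  expect_equal(select_altered_genes(mix2)$selected, sel$selected)
})

test_that("planted high-rate genes are selected and validate bimodality", {
  planted <- setNames(rep(30, 5), sprintf("G%03d", 1:5))
  cfg <- sim_config(
    seed = 7,
    cohorts = data.frame(cancer_type = "AA", n_patients = 500L),
    genes = make_annotations(4, 6, 10),
    base_rates = c(mrna_up = 0.01, mrna_down = 0.01),
    planted_alteration_genes = planted
  )
  calls <- gen_alteration_calls(cfg)
  alt <- alteration_layer(calls, cfg$cohorts, cfg$genes)
  gm <- alt$freq$gene_means
  expect_equal(gm$gene[which.max(gm$mean_f_gene)],
               gm$gene[which.max(gm$mean_f_gene * (gm$gene %in%
                                                     names(planted)))])
  expect_true(all(names(planted) %in% alt$selection$selected))
  # above-vs-below-cutoff Mann-Whitney on the planted bimodal structure
  expect_lt(alt$selection$test$p_value, 0.001)
})

test_that("Mann-Whitney matches exact enumeration on all small inputs", {
  # frozen example: x = {1,2}, y = {3,4} -> U = 0, exact p = 2/6
  tst <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(tst$statistic, 0)
  expect_equal(tst$p_value, 1 / 3, tolerance = 1e-12)

  # identical multisets give p = 1
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1)

  # random small samples (with ties) against the brute-force oracle
  set.seed(99)
  for (i in 1:40) {
    n1 <- sample(1:5, 1)
    n2 <- sample(1:5, 1)
    x <- sample(1:4, n1, replace = TRUE)
    y <- sample(1:4, n2, replace = TRUE)
    got <- suppressWarnings(mann_whitney_u(x, y))
    expect_equal(got$p_value, oracle_mw_exact_p(x, y), tolerance = 1e-12,
                 label = sprintf("case %d", i))
  }
})

test_that("Mann-Whitney normal approximation matches wilcox.test", {
  skip_if_not_installed("stats")
  set.seed(123)
  for (i in 1:10) {
    x <- rnorm(30)
    y <- rnorm(30, mean = 0.3)
    got <- mann_whitney_u(x, y)
    ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-6)
    expect_equal(got$statistic, unname(ref$statistic))
  }
  # tied data uses the tie-corrected variance
  x <- sample(1:5, 40, replace = TRUE)
  y <- sample(1:5, 35, replace = TRUE)
  got <- mann_whitney_u(x, y)
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-6)
})

test_that("degenerate Mann-Whitney input warns and returns p = 1", {
  expect_warning(tst <- mann_whitney_u(c(2, 2), c(2, 2, 2)), "identical")
  expect_equal(tst$p_value, 1)
})

test_that("alteration-type comparison separates an extreme type", {
  genes <- sprintf("G%02d", 1:10)
  counts <- data.frame(gene = genes, cancer_type = "AA",
                       alteration_type = "mrna_up", n_events = 50L,
                       stringsAsFactors = FALSE)
  cohorts <- data.frame(cancer_type = "AA", n_patients = 100L)
  freq <- normalize_frequency(counts, cohorts, genes = genes)
  expect_error(compare_alteration_types(freq), "at least 2")

  counts2 <- rbind(counts,
                   data.frame(gene = genes, cancer_type = "AA",
                              alteration_type = "fusion", n_events = 1L,
                              stringsAsFactors = FALSE))
  freq2 <- normalize_frequency(counts2, cohorts, genes = genes)
  res <- compare_alteration_types(freq2, alpha = 0.001)
  expect_equal(nrow(res), 6L)
  expect_equal(unique(res$alpha_adjusted), 0.001 / 6, tolerance = 1e-12)
  expect_true(res$significant[res$alteration_type == "mrna_up"])
})

test_that("cohort ranking is descending with alphabetical ties", {
  genes <- c("G1", "G2")
  counts <- data.frame(
    gene = c("G1", "G1", "G1"),
    cancer_type = c("B", "A", "C"),
    alteration_type = "mrna_up",
    n_events = c(89L, 89L, 87L),
    stringsAsFactors = FALSE)
  cohorts <- data.frame(cancer_type = c("A", "B", "C"),
                        n_patients = rep(1000L, 3))
  freq <- normalize_frequency(counts, cohorts, genes = genes)
  rk <- rank_cohorts(freq)
  expect_equal(rk$cancer_type, c("A", "B", "C"))  # tie A/B -> alphabetical
  single <- normalize_frequency(counts[2, ],
                                cohorts[1, , drop = FALSE], genes = genes)
  expect_equal(nrow(rank_cohorts(single)), 1L)
})

test_that("category breakdown reproduces stated percentages", {
  ann <- make_annotations(4, 15, 31)
  sel <- ann$gene  # a 50-gene selection with (4, 15, 31)
  bd <- category_breakdown(sel, ann)
  expect_equal(bd$pct, c(8, 30, 62))

  three <- make_annotations(1, 1, 1)
  bd3 <- category_breakdown(three$gene, three)
  expect_equal(bd3$pct, rep(100 / 3, 3))

  expect_warning(bd0 <- category_breakdown(character(0), ann), "empty")
  expect_true(all(bd0$n == 0))
})
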