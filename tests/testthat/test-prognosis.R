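test_that("KM estimate matches the closed form on uncensored data", {
  curve <- km_estimate(c(1, 2, 3, 4), rep(TRUE, 4))
  expect_equal(curve$survival, c(0.75, 0.5, 0.25, 0))

  all_cens <- km_estimate(c(1, 2, 3), rep(FALSE, 3))
  expect_true(all(all_cens$survival == 1))

  expect_error(km_estimate(c(-1, 2), c(TRUE, TRUE)), "negative")

  # uncensored data: S(t_k) = 1 - k/n at each event time (property)
  set.seed(5)
  t <- sort(sample(1:100, 20))
  curve <- km_estimate(t, rep(TRUE, 20))
  expect_equal(curve$survival, 1 - seq_len(20) / 20)
})

test_that("KM estimate matches a hand-computed censored fixture", {
  # times: 1(event) 2(censor) 3(event) 3(event) 5(censor) 6(event)
  time <- c(1, 2, 3, 3, 5, 6)
  event <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)
  curve <- km_estimate(time, event)
  # hand product-limit: S(1)=5/6; S(3)=5/6*(1-2/4)=5/12; S(6)=5/12*(1-1/1)=0
  expect_equal(curve$survival[curve$time == 1], 5 / 6)
  expect_equal(curve$survival[curve$time == 3], 5 / 12)
  expect_equal(curve$survival[curve$time == 6], 0)
  expect_equal(curve$n_risk, c(6L, 5L, 4L, 2L, 1L))
})

test_that("KM curve and median agree with the survival package", {
  skip_if_not_installed("survival")
  set.seed(31)
  time <- rexp(80, rate = 0.02)
  event <- runif(80) < 0.7
  curve <- km_estimate(time, event)
  ref <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "log-log")
  expect_equal(curve$survival, ref$surv, tolerance = 1e-9)
  pos <- ref$surv > 0   # at S = 0 the relative std.err is undefined
  expect_equal(curve$std_err[pos], (ref$surv * ref$std.err)[pos],
               tolerance = 1e-9)

  med <- km_median(curve)
  ref_tab <- summary(ref)$table
  expect_equal(med$median, unname(ref_tab["median"]), tolerance = 1e-9)
  expect_equal(med$ci_low, unname(ref_tab["0.95LCL"]), tolerance = 1e-9)
  expect_equal(med$ci_high, unname(ref_tab["0.95UCL"]), tolerance = 1e-9)
})

test_that("median rules: first time S <= 0.5, NA when never reached", {
  med <- km_median(km_estimate(1:5, rep(TRUE, 5)))
  expect_equal(med$median, 3)  # S(3) = 0.4 is the first at or below 0.5

  shallow <- km_estimate(c(1, 2, 3, 4, 5),
                         c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(min(shallow$survival), 0.6)
  expect_true(is.na(km_median(shallow)$median))
})

test_that("log-rank test: identity, symmetry, reference agreement", {
  a <- data.frame(time = c(2, 4, 6, 8), event = c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(logrank_test(a, a)$statistic, 0)
  expect_equal(logrank_test(a, a)$p_value, 1)

  set.seed(77)
  b <- data.frame(time = rexp(40, 0.03), event = runif(40) < 0.8)
  c_ <- data.frame(time = rexp(40, 0.06), event = runif(40) < 0.8)
  expect_equal(logrank_test(b, c_)$statistic, logrank_test(c_, b)$statistic)

  skip_if_not_installed("survival")
  ref <- survival::survdiff(
    survival::Surv(time, event) ~ grp,
    data = rbind(cbind(b, grp = 0), cbind(c_, grp = 1)))
  got <- logrank_test(b, c_)
  expect_equal(got$statistic, unname(ref$chisq), tolerance = 1e-6)
  expect_equal(got$p_value,
               pchisq(ref$chisq, 1, lower.tail = FALSE), tolerance = 1e-6)
})

test_that("log-rank statistic is invariant to monotone time transforms", {
  set.seed(8)
  a <- data.frame(time = rexp(30, 0.05), event = runif(30) < 0.7)
  b <- data.frame(time = rexp(30, 0.1), event = runif(30) < 0.7)
  s1 <- logrank_test(a, b)$statistic
  tr <- function(df) data.frame(time = log1p(df$time)^2, event = df$event)
  s2 <- logrank_test(tr(a), tr(b))$statistic
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("best-separation scan finds planted effects and handles degeneracy", {
  cfg <- tiny_config(seed = 11, censor_rate = 0.2)
  rec <- gen_survival_cohort(cfg, "expression", n = 500L, beta = log(3))
  scan <- best_separation_scan(rec$expression, rec$time, rec$event)
  expect_equal(scan$direction, "unfavorable")
  expect_true(scan$unfavorable_flag)
  expect_lt(scan$logrank_p, 0.001)

  # argmin property: scanned p is never worse than the median split
  median_split <- function(expr, time, event) {
    low <- expr <= quantile(expr, 0.5, names = FALSE)
    logrank_test(data.frame(time = time[low], event = event[low]),
                 data.frame(time = time[!low], event = event[!low]))$p_value
  }
  for (seed in 1:5) {
    set.seed(seed)
    expr <- rnorm(100)
    time <- rexp(100, 0.03 * exp(0.4 * expr))
    event <- runif(100) < 0.8
    scan <- best_separation_scan(expr, time, event)
    expect_lte(scan$logrank_p, median_split(expr, time, event) + 1e-12)
  }

  expect_warning(
    res <- best_separation_scan(rep(1, 30), rexp(30), rep(TRUE, 30)),
    "no valid")
  expect_true(is.na(res$best_cutoff))
  expect_false(res$unfavorable_flag)

  expect_error(best_separation_scan(rnorm(10), rexp(10), rep(TRUE, 10)),
               "at least 20")
})

test_that("flag rate is non-decreasing in the planted effect size", {
  cfg <- tiny_config(seed = 3, censor_rate = 0.2)
  rate_for_beta <- function(beta, n_rep = 8) {
    hits <- 0L
    for (k in seq_len(n_rep)) {
      cfg_k <- tiny_config(seed = 1000 + k, censor_rate = 0.2)
      rec <- gen_survival_cohort(cfg_k, "expression", n = 300L, beta = beta)
      scan <- best_separation_scan(rec$expression, rec$time, rec$event)
      if (isTRUE(scan$unfavorable_flag)) hits <- hits + 1L
    }
    hits / n_rep
  }
  rates <- vapply(c(0, 0.5, 1.1), rate_for_beta, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_equal(rates[3], 1)  # log HR 1.1 at n = 300 is always detected
})

test_that("prognosis layer summarises per-gene unfavorable significance", {
  cfg <- tiny_config(seed = 21, censor_rate = 0.2)
  records <- do.call(rbind, lapply(c("GA", "GB"), function(g) {
    beta <- if (g == "GA") 1.1 else 0
    cbind(gene = g,
          gen_survival_cohort(cfg, "expression", gene = g, beta = beta,
                              n = 400L),
          stringsAsFactors = FALSE)
  }))
  prog <- prognosis_layer(records)
  gs <- prog$gene_summary
  expect_true(gs$unfavorable_flag[gs$gene == "GA"])
  expect_false(gs$unfavorable_flag[gs$gene == "GB"])
  expect_lt(gs$min_unfavorable_p[gs$gene == "GA"], 0.001)
})
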