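#' Kaplan-Meier product-limit estimate
#'
#' Computes the product-limit survival curve with Greenwood variance.
#' Censored times reduce the risk set without producing steps.
#'
#' @param time Non-negative follow-up times (months).
#' @param event Logical; TRUE when the death was observed.
#' @return An object of class `km_curve`: a data.frame with one row per
#'   distinct observed time (time, n_risk, n_event, n_censor, survival,
#'   std_err), where `std_err` is the Greenwood standard error of S(t).
#' @export
km_estimate <- function(time, event) {
  if (is.data.frame(time)) {
    event <- time$event
    time <- time$time
  }
  stopifnot(length(time) == length(event), length(time) >= 1)
  if (any(time < 0)) stop("negative survival time", call. = FALSE)
  event <- as.logical(event)
  ord <- order(time)
  time <- time[ord]
  event <- event[ord]
  ut <- unique(time)
  n <- length(time)
  n_risk <- n - findInterval(ut, time, left.open = TRUE)
  n_event <- as.integer(tapply(event, factor(time, levels = ut), sum))
  n_censor <- as.integer(tapply(!event, factor(time, levels = ut), sum))
  surv <- cumprod(1 - n_event / n_risk)
  ## Greenwood: var(S) = S^2 * cumsum(d / (n (n - d)))
  gw_term <- ifelse(n_risk > n_event, n_event / (n_risk * (n_risk - n_event)),
                    0)
  gw <- cumsum(gw_term)
  std_err <- surv * sqrt(gw)
  out <- data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                    n_censor = n_censor, survival = surv,
                    std_err = std_err, greenwood = gw)
  class(out) <- c("km_curve", "data.frame")
  out
}

## internal: survival probability at time t (right-continuous step function)
km_survival_at <- function(curve, t) {
  idx <- findInterval(t, curve$time)
  ifelse(idx == 0, 1, curve$survival[pmax(idx, 1)])
}

## internal: pointwise log-log confidence band for S(t)
km_loglog_ci <- function(curve, conf_level = 0.95) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  s <- curve$survival
  se_ll <- ifelse(s > 0 & s < 1, sqrt(curve$greenwood) / abs(log(s)), NA)
  lower <- ifelse(is.na(se_ll), ifelse(s %in% c(0, 1), s, NA),
                  s^exp(z * se_ll))
  upper <- ifelse(is.na(se_ll), ifelse(s %in% c(0, 1), s, NA),
                  s^exp(-z * se_ll))
  list(lower = lower, upper = upper)
}

#' Median survival with confidence interval
#'
#' The median is the smallest observed time with S(t) <= 0.5 (NA when the
#' curve never reaches 0.5). The confidence interval follows the
#' Brookmeyer-Crowley construction on the log(-log) scale: each bound is
#' the first time the corresponding pointwise log-log confidence limit for
#' S(t) drops to 0.5 or below.
#'
#' @param curve A `km_curve`.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `median`, `ci_low`, `ci_high` (months; NA when
#'   undefined).
#' @export
km_median <- function(curve, conf_level = 0.95) {
  stopifnot(inherits(curve, "km_curve"))
  first_at_or_below <- function(values) {
    hit <- which(!is.na(values) & values <= 0.5)
    if (length(hit) == 0) NA_real_ else curve$time[hit[1]]
  }
  ci <- km_loglog_ci(curve, conf_level)
  list(median = first_at_or_below(curve$survival),
       ci_low = first_at_or_below(ci$lower),
       ci_high = first_at_or_below(ci$upper))
}

#' Two-group log-rank test
#'
#' Standard 1-degree-of-freedom log-rank chi-square from observed vs
#' expected event counts at each pooled event time, with the
#' hypergeometric variance.
#'
#' @param group_a,group_b data.frames with columns time, event.
#' @return A `cr_test` with the chi-square statistic.
#' @export
logrank_test <- function(group_a, group_b) {
  t1 <- group_a$time; e1 <- as.logical(group_a$event)
  t2 <- group_b$time; e2 <- as.logical(group_b$event)
  n1 <- length(t1); n2 <- length(t2)
  if (n1 == 0 || n2 == 0) stop("both groups must be non-empty", call. = FALSE)
  et <- sort(unique(c(t1[e1], t2[e2])))
  if (length(et) == 0) {
    return(test_result(0, 1, n1, n2, "log-rank (no events)"))
  }
  s1 <- sort(t1); s2 <- sort(t2)
  r1 <- n1 - findInterval(et, s1, left.open = TRUE)
  r2 <- n2 - findInterval(et, s2, left.open = TRUE)
  d1 <- as.integer(tapply(rep(1L, sum(e1)),
                          factor(t1[e1], levels = et), sum))
  d1[is.na(d1)] <- 0L
  d2 <- as.integer(tapply(rep(1L, sum(e2)),
                          factor(t2[e2], levels = et), sum))
  d2[is.na(d2)] <- 0L
  d <- d1 + d2
  r <- r1 + r2
  expected1 <- d * r1 / r
  v <- ifelse(r > 1, d * (r1 / r) * (1 - r1 / r) * (r - d) / (r - 1), 0)
  V <- sum(v)
  if (V <= 0) {
    return(test_result(0, 1, n1, n2, "log-rank (degenerate)"))
  }
  chi2 <- (sum(d1) - sum(expected1))^2 / V
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  test_result(chi2, p, n1, n2, "log-rank")
}
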