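# Objective response rate with exact binomial confidence intervals, exact
# (optionally stratified) comparison of response rates, and Kaplan-Meier /
# Cox progression-free-survival comparison between biomarker subgroups.

#' Objective response rate with exact (Clopper-Pearson) confidence interval
#'
#' ORR = responders / total.  The two-sided exact interval inverts the
#' equal-tailed binomial tests via the beta-quantile closed form:
#' lower = `qbeta(alpha/2, x, n - x + 1)` (0 when x = 0),
#' upper = `qbeta(1 - alpha/2, x + 1, n - x)` (1 when x = n).
#'
#' @param responders Number of responders (best objective response CR/PR).
#' @param total Number of patients, > 0.
#' @param level Confidence level (default 0.95).
#' @return Object of class `orr_result`: `responders`, `total`, `orr`,
#'   `ci_low`, `ci_high` (proportions).  The print method displays percent
#'   values rounded to two significant figures.
#' @export
orr_exact_ci <- function(responders, total, level = 0.95) {
  if (total <= 0) stop("total must be positive", call. = FALSE)
  if (responders < 0 || responders > total) {
    stop("responders must lie in [0, total]", call. = FALSE)
  }
  alpha <- 1 - level
  lo <- if (responders == 0) 0 else
    stats::qbeta(alpha / 2, responders, total - responders + 1)
  hi <- if (responders == total) 1 else
    stats::qbeta(1 - alpha / 2, responders + 1, total - responders)
  structure(
    list(responders = responders, total = total,
         orr = responders / total, ci_low = lo, ci_high = hi, level = level),
    class = "orr_result"
  )
}

#' @export
print.orr_result <- function(x, ...) {
  pct <- function(p) formatC(signif(100 * p, 2), format = "fg")
  cat(sprintf("ORR: %d/%d = %s%% (%.0f%% CI, %s-%s)\n",
              x$responders, x$total, pct(x$orr), 100 * x$level,
              pct(x$ci_low), pct(x$ci_high)))
  invisible(x)
}

#' Compare response rates between two groups (exact conditional test)
#'
#' Without strata this is the two-sided Fisher exact test on the 2x2
#' responder table.  With strata, an exact conditional test: conditioning on
#' each stratum's responder margin, the null distribution of the total
#' number of group-A responders is the convolution of per-stratum central
#' hypergeometric distributions; the two-sided p-value sums the
#' probabilities of all outcomes no more probable than the observed one
#' (the same point-probability rule as the Fisher test, to which the
#' single-stratum case reduces exactly).  Strata in which either group is
#' absent carry no information and are dropped with a warning.
#'
#' @param responders_a,total_a Responder count and size of group A.
#' @param responders_b,total_b Responder count and size of group B.
#' @param strata Optional data frame with columns `responders_a`, `total_a`,
#'   `responders_b`, `total_b`, one row per stratum (overrides the scalar
#'   arguments).
#' @return Two-sided p-value.
#' @export
compare_orr <- function(responders_a, total_a, responders_b, total_b,
                        strata = NULL) {
  if (is.null(strata)) {
    strata <- data.frame(responders_a = responders_a, total_a = total_a,
                         responders_b = responders_b, total_b = total_b)
  }
  keep <- strata$total_a > 0 & strata$total_b > 0
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " stratum/strata with an empty group")
    strata <- strata[keep, , drop = FALSE]
  }
  if (nrow(strata) == 0) stop("no informative strata", call. = FALSE)
  if (nrow(strata) == 1L) {
    # single stratum: the exact conditional test is the Fisher test
    return(suppressWarnings(min(1, fisher_exact_2x2(matrix(
      c(strata$responders_a, strata$total_a - strata$responders_a,
        strata$responders_b, strata$total_b - strata$responders_b), 2, 2)))))
  }
  resp <- strata$responders_a + strata$responders_b
  # exact null distribution of T = total responders in group A
  lo_s <- pmax(0L, resp - strata$total_b)
  hi_s <- pmin(strata$total_a, resp)
  probs <- 1
  for (s in seq_len(nrow(strata))) {
    ps <- stats::dhyper(lo_s[s]:hi_s[s], strata$total_a[s],
                        strata$total_b[s], resp[s])
    probs <- if (length(probs) == 1 && length(ps) == 1) probs * ps
    else outer_convolve(probs, ps)
  }
  support <- sum(lo_s) + seq_along(probs) - 1L
  t_obs <- sum(strata$responders_a)
  p_obs <- probs[match(t_obs, support)]
  if (is.na(p_obs)) stop("observed table inconsistent with margins",
                         call. = FALSE)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

outer_convolve <- function(p, q) {
  out <- numeric(length(p) + length(q) - 1L)
  for (i in seq_along(p)) {
    idx <- i + seq_along(q) - 1L
    out[idx] <- out[idx] + p[i] * q
  }
  out
}

#' Kaplan-Meier survival curve with median
#'
#' Product-limit estimator (via [survival::survfit()]); the median is the
#' smallest observed time at which the survival estimate drops to 0.5 or
#' below, absent (NA) when the curve never crosses 0.5.
#'
#' @param times Positive event/censoring times (months).
#' @param events Logical (or 0/1): event observed vs censored.
#' @return Object of class `km_curve`: data frame `curve` with `time`,
#'   `n_risk`, `n_event`, `surv`; and `median`.
#' @export
km_curve <- function(times, events) {
  if (length(times) == 0) stop("empty input", call. = FALSE)
  if (any(times <= 0)) stop("times must be positive", call. = FALSE)
  events <- as.logical(events)
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  curve <- data.frame(time = sf$time, n_risk = sf$n.risk,
                      n_event = sf$n.event, surv = sf$surv)
  med <- with(curve, if (any(surv <= 0.5)) min(time[surv <= 0.5]) else NA_real_)
  structure(list(curve = curve, median = med, n = length(times),
                 n_events = sum(events)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, median = %s\n",
              x$n, x$n_events,
              if (is.na(x$median)) "not reached" else sprintf("%.2f", x$median)))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, xlab = "time (months)", ylab = "survival",
                          ...) {
  with(x$curve, graphics::plot(
    stats::stepfun(time, c(1, surv)), do.points = FALSE,
    xlab = xlab, ylab = ylab, ylim = c(0, 1), main = "", ...))
  invisible(x)
}

#' Compare survival between two groups
#'
#' Log-rank test ([survival::survdiff()]) plus a single-covariate Cox
#' proportional-hazards fit with Efron tie handling for the hazard ratio of
#' group B relative to group A, with a Wald confidence interval.
#'
#' @param times_a,events_a Times and event indicators for group A.
#' @param times_b,events_b Times and event indicators for group B.
#' @param labels Group labels (length 2), for display.
#' @param level Confidence level for the hazard-ratio interval.
#' @return Object of class `survival_comparison`: medians, `hazard_ratio`
#'   (B vs A), `hr_ci`, `logrank_p`, and the underlying fits.
#' @export
compare_survival <- function(times_a, events_a, times_b, events_b,
                             labels = c("A", "B"), level = 0.95) {
  if (length(times_a) == 0 || length(times_b) == 0) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  events_a <- as.logical(events_a); events_b <- as.logical(events_b)
  if (sum(events_a) + sum(events_b) == 0) {
    stop("no events observed in either group", call. = FALSE)
  }
  time <- c(times_a, times_b)
  event <- c(events_a, events_b)
  group <- factor(rep(labels, c(length(times_a), length(times_b))),
                  levels = labels)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  logrank_p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  cx <- survival::coxph(survival::Surv(time, event) ~ group, ties = "efron")
  beta <- unname(stats::coef(cx)[1])
  se <- sqrt(stats::vcov(cx)[1, 1])
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(
    list(groups = labels,
         median_a = km_curve(times_a, events_a)$median,
         median_b = km_curve(times_b, events_b)$median,
         hazard_ratio = exp(beta),
         hr_ci = exp(beta + c(-1, 1) * z * se),
         logrank_p = logrank_p,
         cox_fit = cx, level = level),
    class = "survival_comparison"
  )
}

#' @export
print.survival_comparison <- function(x, ...) {
  fmt_med <- function(m) if (is.na(m)) "NR" else sprintf("%.1f", m)
  cat(sprintf("PFS %s vs %s: median %s vs %s months\n",
              x$groups[2], x$groups[1], fmt_med(x$median_b),
              fmt_med(x$median_a)))
  cat(sprintf("HR (%s vs %s) = %.2f (%.0f%% CI, %.3g-%.3g), log-rank p = %.3g\n",
              x$groups[2], x$groups[1], x$hazard_ratio, 100 * x$level,
              x$hr_ci[1], x$hr_ci[2], x$logrank_p))
  invisible(x)
}
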