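# Bisection oracle for the Clopper-Pearson bounds: solve the two binomial
# tail equations directly.
cp_oracle <- function(x, n, level = 0.95) {
  a <- (1 - level) / 2
  lo <- if (x == 0) 0 else
    uniroot(function(p) 1 - pbinom(x - 1, n, p) - a,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  hi <- if (x == n) 1 else
    uniroot(function(p) pbinom(x, n, p) - a,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(lo, hi)
}

test_that("exact ORR interval matches the tail-equation oracle and binom.test", {
  for (x in c(0, 1, 3, 5, 10)) {
    o <- orr_exact_ci(x, 10)
    expect_equal(c(o$ci_low, o$ci_high), cp_oracle(x, 10), tolerance = 1e-8)
    bt <- binom.test(x, 10)$conf.int
    expect_equal(c(o$ci_low, o$ci_high), as.numeric(bt), tolerance = 1e-8)
  }
  o19 <- orr_exact_ci(19, 19)
  expect_equal(o19$orr, 1)
  expect_equal(o19$ci_high, 1)
  expect_error(orr_exact_ci(1, 0), "positive")
  expect_error(orr_exact_ci(5, 4), "responders")
})

test_that("CI bounds are nondecreasing in the responder count", {
  for (n in c(5, 19, 47)) {
    lows <- sapply(0:n, function(x) orr_exact_ci(x, n)$ci_low)
    highs <- sapply(0:n, function(x) orr_exact_ci(x, n)$ci_high)
    expect_true(all(diff(lows) >= 0))
    expect_true(all(diff(highs) >= 0))
  }
})

test_that("unstratified ORR comparison is exactly the Fisher test", {
  set.seed(13)
  for (i in 1:25) {
    na <- sample(3:40, 1); nb <- sample(3:40, 1)
    xa <- sample(0:na, 1); xb <- sample(0:nb, 1)
    got <- compare_orr(xa, na, xb, nb)
    want <- suppressWarnings(
      fisher_exact_2x2(matrix(c(xa, na - xa, xb, nb - xb), 2, 2)))
    expect_identical(got, min(1, want))
  }
  expect_equal(compare_orr(2, 18, 0, 5), 1.0)
})

# Brute-force oracle for the stratified exact conditional test: enumerate
# every combination of per-stratum group-A responder counts.
stratified_oracle <- function(strata) {
  resp <- strata$responders_a + strata$responders_b
  ranges <- lapply(seq_len(nrow(strata)), function(s) {
    max(0, resp[s] - strata$total_b[s]):min(strata$total_a[s], resp[s])
  })
  grid <- do.call(expand.grid, ranges)
  probs <- apply(grid, 1, function(x) {
    prod(dhyper(x, strata$total_a, strata$total_b, resp))
  })
  t_all <- rowSums(grid)
  t_obs <- sum(strata$responders_a)
  pt <- tapply(probs, t_all, sum)
  p_obs <- pt[[as.character(t_obs)]]
  sum(pt[pt <= p_obs * (1 + 1e-7)])
}

test_that("stratified exact conditional test matches enumeration", {
  set.seed(31)
  for (i in 1:10) {
    k <- sample(2:3, 1)
    strata <- data.frame(total_a = sample(3:12, k, TRUE),
                         total_b = sample(3:12, k, TRUE))
    strata$responders_a <- sapply(strata$total_a, function(n) sample(0:n, 1))
    strata$responders_b <- sapply(strata$total_b, function(n) sample(0:n, 1))
    got <- compare_orr(strata = strata)
    expect_equal(got, min(1, stratified_oracle(strata)), tolerance = 1e-10)
  }
  # a stratum with an empty group is dropped with a warning
  s <- data.frame(responders_a = c(2, 1), total_a = c(10, 5),
                  responders_b = c(1, 0), total_b = c(8, 0))
  expect_warning(p <- compare_orr(strata = s), "dropping")
  expect_equal(p, compare_orr(2, 10, 1, 8))
})

test_that("Kaplan-Meier curve matches empirical survival and closed forms", {
  km <- km_curve(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$curve$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$median, 2)

  cens <- km_curve(c(1, 2, 3), c(FALSE, FALSE, FALSE))
  expect_true(all(cens$curve$surv == 1))
  expect_true(is.na(cens$median))

  # without censoring, S(t) = 1 - ECDF(t) at every event time
  set.seed(8)
  t <- rexp(200, 0.3)
  km2 <- km_curve(t, rep(TRUE, 200))
  expect_equal(km2$curve$surv, 1 - ecdf(t)(km2$curve$time))

  # exponential closed form: median ~ ln 2 / lambda
  t3 <- rexp(2000, rate = 0.5)
  km3 <- km_curve(t3, rep(TRUE, 2000))
  expect_lt(abs(km3$median - log(2) / 0.5) / (log(2) / 0.5), 0.05)

  expect_error(km_curve(numeric(0), logical(0)), "empty")
  expect_error(km_curve(c(0, 1), c(TRUE, TRUE)), "positive")
})

# Hand log-rank oracle: accumulate observed-minus-expected and the
# hypergeometric variance at each distinct event time.
logrank_oracle <- function(t1, e1, t2, e2) {
  times <- sort(unique(c(t1[e1], t2[e2])))
  o_minus_e <- 0; v <- 0
  for (tt in times) {
    n1 <- sum(t1 >= tt); n2 <- sum(t2 >= tt); n <- n1 + n2
    d1 <- sum(t1 == tt & e1); d2 <- sum(t2 == tt & e2); d <- d1 + d2
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  pchisq(o_minus_e^2 / v, 1, lower.tail = FALSE)
}

test_that("survival comparison reproduces a hand-computed log-rank test", {
  t1 <- c(1, 3, 4, 6, 8); e1 <- c(TRUE, TRUE, FALSE, TRUE, TRUE)
  t2 <- c(2, 3, 5, 7, 9); e2 <- c(TRUE, FALSE, TRUE, TRUE, FALSE)
  cmp <- compare_survival(t1, e1, t2, e2)
  expect_equal(cmp$logrank_p, logrank_oracle(t1, e1, t2, e2),
               tolerance = 1e-10)
})

test_that("identical groups give HR 1 and log-rank p 1", {
  t <- c(2, 4, 6, 8, 10); e <- c(TRUE, TRUE, FALSE, TRUE, TRUE)
  cmp <- compare_survival(t, e, t, e)
  expect_equal(cmp$hazard_ratio, 1, tolerance = 1e-8)
  expect_equal(cmp$logrank_p, 1, tolerance = 1e-8)
  expect_equal(cmp$median_a, cmp$median_b)

  expect_error(compare_survival(numeric(0), logical(0), t, e), "nonempty")
  expect_error(compare_survival(c(1, 2), c(FALSE, FALSE),
                                c(3, 4), c(FALSE, FALSE)), "no events")
})
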