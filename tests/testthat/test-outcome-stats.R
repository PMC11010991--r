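test_that("the product-limit estimator matches hand-computed tables", {
  # three deaths, no censoring
  km <- km_estimate(tibble::tibble(time_months = c(1, 2, 3), event = 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  # all censored: survival never drops
  km_c <- km_estimate(tibble::tibble(time_months = c(1, 2, 3), event = 0))
  expect_true(all(km_c$survival == 1))
  # six records with mixed censoring, product-limit worked by hand:
  # t=1 (6 at risk, 1 death) -> 5/6; t=3 (4, 1) -> 5/8; t=5 (2, 1) -> 5/16;
  # t=6 (1, 1) -> 0
  km6 <- km_estimate(tibble::tibble(
    time_months = c(1, 2, 3, 4, 5, 6),
    event = c(1, 0, 1, 0, 1, 1)
  ))
  ev <- km6[km6$n_event > 0, ]
  expect_equal(ev$time, c(1, 3, 5, 6))
  expect_equal(ev$survival, c(5 / 6, 5 / 8, 5 / 16, 0))
})

test_that("the KM estimate equals the empirical survivor without censoring", {
  set.seed(6)
  t <- round(rexp(40, 0.1), 3)
  km <- km_estimate(tibble::tibble(time_months = t, event = 1))
  emp <- vapply(km$time, function(tt) mean(t > tt), numeric(1))
  expect_equal(km$survival, emp)
  expect_error(km_estimate(tibble::tibble(time_months = c(1, -2),
                                          event = 1)), "positive")
})

test_that("the log-rank test matches a from-scratch O-E computation", {
  set.seed(15)
  records <- tibble::tibble(
    time_months = round(rexp(40, 0.08), 2) + 0.01,
    event = rbinom(40, 1, 0.7),
    group = rep(c("low", "high"), 20)
  )
  got <- logrank_test(records)
  want <- oracle_logrank(records$time_months, records$event, records$group)
  expect_equal(got$statistic, want, tolerance = 1e-6)
  expect_equal(got$p_value, pchisq(want, 1, lower.tail = FALSE),
               tolerance = 1e-6)
  # label swap leaves the statistic unchanged
  swapped <- dplyr::mutate(records,
                           group = ifelse(group == "low", "high", "low"))
  expect_equal(logrank_test(swapped)$statistic, got$statistic)
  # identical groups: statistic 0, p = 1
  dup <- tibble::tibble(
    time_months = rep(c(2, 4, 6), 2), event = rep(c(1, 0, 1), 2),
    group = rep(c("a", "b"), each = 3)
  )
  null <- logrank_test(dup)
  expect_equal(null$statistic, 0, tolerance = 1e-12)
  expect_equal(null$p_value, 1, tolerance = 1e-12)
})

test_that("log-rank p-values are approximately uniform under the null", {
  ps <- vapply(1:500, function(s) {
    set.seed(1000 + s)
    rec <- tibble::tibble(
      time_months = rexp(40, 0.1),
      event = rbinom(40, 1, 0.8),
      group = rep(c("a", "b"), 20)
    )
    logrank_test(rec)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("dichotomization rules split patients as documented", {
  expect_identical(as.character(dichotomize(c(1, 2, 3, 4))),
                   c("low", "low", "high", "high"))
  # ties at the median go to low
  expect_identical(as.character(dichotomize(c(1, 2, 2, 5))),
                   c("low", "low", "low", "high"))
  # shift invariance
  expect_identical(dichotomize(c(1, 2, 3, 4) + 100),
                   dichotomize(c(1, 2, 3, 4)))
  # short/long-term survivor split in months: <12 short, >24 long
  sl <- dichotomize(c(6, 18, 36), rule = "short_long_term")
  expect_identical(as.character(sl), c("short", NA, "long"))
  expect_error(dichotomize(rep(2, 4)), "no split")
  thr <- dichotomize(c(1, 5, 9), rule = "threshold", threshold = 4)
  expect_identical(as.character(thr), c("low", "high", "high"))
})

test_that("group comparisons reproduce closed-form t statistics", {
  x <- c(5.1, 4.8, 5.6, 5.0, 4.7)
  y <- c(6.0, 6.3, 5.8, 6.4, 6.1)
  got <- compare_groups(c(x, y), rep(c("x", "y"), each = 5), "two_sample_t")
  sp2 <- ((4 * var(x)) + (4 * var(y))) / 8
  t_manual <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  expect_equal(abs(got$statistic), abs(t_manual), tolerance = 1e-9)
  # identical groups -> zero-variance convention
  expect_message(
    same <- compare_groups(rep(1, 6), rep(c("a", "b"), 3), "two_sample_t"),
    "zero variance"
  )
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # paired design matches t.test on differences
  got_p <- compare_groups(c(x, y), rep(c("x", "y"), each = 5), "paired_t")
  expect_equal(got_p$statistic,
               unname(t.test(x, y, paired = TRUE)$statistic),
               tolerance = 1e-9)
})

test_that("ANOVA emits Bonferroni-adjusted pairwise comparisons", {
  set.seed(2)
  v <- c(rnorm(8, 0), rnorm(8, 1), rnorm(8, 3))
  g <- rep(c("a", "b", "c"), each = 8)
  out <- compare_groups(v, g, "anova_bonferroni")
  expect_identical(nrow(out), 4L) # overall F + 3 pairwise
  pw <- out[-1, ]
  expect_identical(nrow(pw), 3L)
  expect_equal(pw$p_adjusted, pmin(1, 3 * pw$p_value))
  an <- summary(aov(v ~ factor(g)))[[1]]
  expect_equal(out$statistic[1], an[["F value"]][1], tolerance = 1e-9)
})

test_that("pearson correlation matches the covariance formula", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  set.seed(8)
  a <- rnorm(20)
  b <- rnorm(20)
  got <- pearson_correlation(a, b)
  manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(got$r, manual, tolerance = 1e-12)
  expect_equal(got$p_value, cor.test(a, b)$p.value, tolerance = 1e-12)
  expect_warning(bad <- pearson_correlation(rep(1, 5), 1:5), "zero variance")
  expect_true(is.na(bad$r))
})

test_that("tests are invariant to patient row order", {
  set.seed(30)
  rec <- tibble::tibble(
    time_months = rexp(30, 0.05), event = rbinom(30, 1, 0.7),
    group = rep(c("low", "high"), 15)
  )
  perm <- rec[sample(30), ]
  expect_equal(logrank_test(rec)$statistic, logrank_test(perm)$statistic)
  expect_equal(km_estimate(rec)$survival, km_estimate(perm)$survival)
})
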