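test_that("KM estimate matches the closed-form product limit", {
  d <- tibble::tibble(pfs_time = c(1, 2, 3), pfs_event = c(1L, 1L, 1L))
  km <- km_estimate(d)
  expect_equal(km$survival, c(1, 2 / 3, 1 / 3, 0))
  expect_equal(km$time, c(0, 1, 2, 3))
  all_cens <- tibble::tibble(pfs_time = c(4, 9), pfs_event = c(0L, 0L))
  expect_true(all(km_estimate(all_cens)$survival == 1))
})

test_that("KM equals the risk-set product oracle on random instances", {
  for (s in 1:10) {
    fx <- random_surv_fixture(25, s)
    d <- tibble::tibble(pfs_time = fx$time, pfs_event = fx$event)
    if (sum(fx$event) == 0) next
    km <- km_estimate(d)
    or <- oracle_km(fx$time, fx$event)
    got <- km$survival[match(or$time, km$time)]
    expect_equal(got, or$surv, tolerance = 1e-12)
    expect_true(all(diff(km$survival) <= 1e-12))   # non-increasing
  }
})

test_that("log-rank is null on identical groups and matches the oracle", {
  d <- tibble::tibble(pfs_time = rep(c(2, 5, 9), 2),
                      pfs_event = rep(c(1L, 0L, 1L), 2),
                      group = rep(c("a", "b"), each = 3))
  lr <- logrank_test(d)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)
  for (s in 1:15) {
    fx <- random_surv_fixture(30, s + 100)
    g <- rep(c("a", "b"), 15)
    if (sum(fx$event) == 0) next
    d <- tibble::tibble(pfs_time = fx$time, pfs_event = fx$event, group = g)
    lr <- logrank_test(d)
    expect_equal(lr$statistic, oracle_logrank2(fx$time, fx$event, g),
                 tolerance = 1e-10)
  }
})

test_that("log-rank is invariant under monotone time transforms", {
  fx <- random_surv_fixture(40, 7)
  g <- rep(c("a", "b"), 20)
  d1 <- tibble::tibble(pfs_time = fx$time, pfs_event = fx$event, group = g)
  d2 <- dplyr::mutate(d1, pfs_time = log1p(pfs_time))
  expect_equal(logrank_test(d1)$statistic, logrank_test(d2)$statistic,
               tolerance = 1e-12)
})

test_that("Cox coefficient is scale-equivariant and matches the likelihood oracle", {
  fx <- random_surv_fixture(50, 9)
  d <- tibble::tibble(pfs_time = fx$time, pfs_event = fx$event,
                      x = fx$score, x2 = 2 * fx$score)
  c1 <- univariate_cox(d, "x")
  c2 <- univariate_cox(d, "x2")
  expect_equal(c2$beta, c1$beta / 2, tolerance = 1e-8)
  for (s in 1:5) {
    fx <- random_surv_fixture(35, s + 300)
    d <- tibble::tibble(pfs_time = fx$time, pfs_event = fx$event,
                        x = fx$score)
    cx <- univariate_cox(d, "x")
    expect_equal(cx$beta, oracle_cox_beta(fx$time, fx$event, fx$score),
                 tolerance = 1e-4)
    expect_true(cx$ci_low < cx$hr && cx$hr < cx$ci_high)
  }
})

test_that("Cox flags monotone likelihood instead of converging", {
  d <- tibble::tibble(pfs_time = c(1, 2, 3, 10, 11, 12),
                      pfs_event = rep(1L, 6),
                      x = c(5, 5, 5, -5, -5, -5))   # perfect separation
  cx <- univariate_cox(d, "x")
  expect_false(cx$converged)
})

test_that("maxstat equals an independent exhaustive survdiff scan", {
  for (s in 1:20) {
    fx <- random_surv_fixture(sample(20:60, 1), s + 500)
    if (sum(fx$event) < 2) next
    ms <- maxstat_cutpoint(fx$score, fx$time, fx$event)
    or <- oracle_maxstat(fx$score, fx$time, fx$event)
    expect_identical(ms$cutpoint, or$cut)
    expect_equal(ms$statistic, or$stat, tolerance = 1e-8)
  }
})

test_that("maxstat respects the group-size guard and beats the median split", {
  fx <- random_surv_fixture(21, 77)
  expect_error(maxstat_cutpoint(fx$score, fx$time, fx$event,
                                min_group_frac = 0.5), "min_group_frac")
  ms <- maxstat_cutpoint(fx$score, fx$time, fx$event)
  med_stat <- ms$candidates$statistic[
    which.min(abs(ms$candidates$cutpoint - median(fx$score)))]
  expect_gte(ms$statistic, med_stat)
})

test_that("maxstat cutpoint group assignment is transform-invariant", {
  fx <- random_surv_fixture(40, 13)
  ms1 <- maxstat_cutpoint(fx$score, fx$time, fx$event)
  ms2 <- maxstat_cutpoint(exp(fx$score), fx$time, fx$event)
  expect_identical(ms1$groups, ms2$groups)
})
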