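test_that("cohort honors configured cluster sizes and is seed-deterministic", {
  cfg <- cohort_config(n_per_cluster = c(157, 36, 212), seed = 11)
  co <- generate_cohort(cfg)
  expect_equal(ncol(co$expression), 405L)
  expect_equal(unname(table(co$truth$true_cluster)), c(157L, 36L, 212L),
               ignore_attr = TRUE)
  co2 <- generate_cohort(cfg)
  expect_identical(co$expression, co2$expression)
  expect_identical(co$clinical, co2$clinical)
  co3 <- generate_cohort(cohort_config(n_per_cluster = c(157, 36, 212),
                                       seed = 12))
  expect_false(identical(co$expression, co3$expression))
})

test_that("a two-pattern design is rejected", {
  expect_error(cohort_config(n_per_cluster = c(100, 100)), "three")
})

test_that("per-cluster regulator means track the configured shifts", {
  # Monte-Carlo check: over replicates the empirical cluster means stay
  # within 3 noise_sd / sqrt(n) of the configured offsets (relative to the
  # cohort-wide baseline)
  devs <- replicate(25, {
    co <- generate_cohort(small_config(seed = sample.int(1e6, 1)))
    e <- co$expression
    cl <- co$truth$true_cluster
    m14 <- tapply(e["METTL14", ], cl, mean)
    k <- tapply(e["KIAA1429", ], cl, mean)
    c(m14[3] - m14[2] - 1, k[2] - k[1] - 1)   # configured gaps are 1
  })
  tol <- 3 * 0.5 / sqrt(30)
  expect_lt(max(abs(rowMeans(devs))), tol)
})

test_that("zero effects leave no recoverable cluster signal", {
  cfg <- cohort_config(n_per_cluster = c(100, 100, 100),
                       regulator_effects = default_regulator_effects(0),
                       n_background = 20, seed = 5)
  co <- generate_cohort(cfg)
  fit <- fit_model_clusters(co$expression, families = "EII", n_init = 2,
                            seed = 6)
  ari <- mclust::adjustedRandIndex(fit$labels, co$truth$true_cluster)
  expect_lt(abs(ari), 0.1)
})

test_that("realized censoring matches the configured rate", {
  cfg <- cohort_config(n_per_cluster = c(150, 100, 150), censor_rate = 0.3,
                       seed = 21)
  co <- generate_cohort(cfg)
  n <- nrow(co$clinical)
  censored <- sum(co$clinical$pfs_event == 0)
  ci <- qbinom(c(0.005, 0.995), n, 0.3)
  expect_gte(censored, ci[1])
  expect_lte(censored, ci[2])
})

test_that("true score is the oracle PCA score of the noiseless CEG means", {
  co <- generate_cohort(small_config(seed = 3))
  by_cl <- tapply(co$truth$true_score, co$truth$true_cluster, unique)
  # noiseless means are shared within a cluster: one score per pattern,
  # ordered pattern 2 < pattern 1 < pattern 3
  expect_true(all(lengths(by_cl) == 1L))
  expect_true(by_cl[["2"]] < by_cl[["1"]] && by_cl[["1"]] < by_cl[["3"]])
})

test_that("moderator scenario plants the intended structure", {
  cfg <- small_config(seed = 9)
  co <- generate_moderator_scenario(cfg)
  pm <- attr(co$truth, "planted_moderator")
  expect_equal(pm$moderator, "MSMB")
  expect_true("MSMB" %in% rownames(co$expression))
  # sign flip of the moderation flips the planted interaction
  up <- generate_moderator_scenario(cfg, sign = 1)
  dn <- generate_moderator_scenario(cfg, sign = -1)
  int_coef <- function(co) {
    r <- scale(co$expression["HNRNPA2B1", ])[, 1]
    m <- scale(co$expression["MSMB", ])[, 1]
    s <- colMeans(co$expression[co$gene_sets$genes[[
      match("Th1 cells", co$gene_sets$name)]], ])
    unname(coef(lm(s ~ r * m))["r:m"])
  }
  expect_gt(int_coef(up), 0)
  expect_lt(int_coef(dn), 0)
})

test_that("write_cohort persists all artifacts", {
  d <- withr::local_tempdir()
  co <- generate_cohort(cohort_config(n_per_cluster = c(10, 10, 10),
                                      n_ceg = 5, n_background = 5, seed = 2))
  write_cohort(co, d)
  expect_true(all(file.exists(file.path(
    d, c("expression.tsv", "clinical.csv", "sets.gmt", "truth.tsv",
         "manifest.json")))))
  m <- read_expression(file.path(d, "expression.tsv"))
  expect_equal(unclass(m)[, ], co$expression[, ], tolerance = 1e-10)
})
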