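test_that("well-separated clouds are recovered perfectly", {
  set.seed(4)
  n <- 40
  X <- rbind(matrix(rnorm(n * 3, 0, 1), n, 3),
             matrix(rnorm(n * 3, 10, 1), n, 3))   # 10 sigma apart
  expr <- t(X)
  rownames(expr) <- paste0("G", 1:3)
  colnames(expr) <- paste0("S", seq_len(2 * n))
  fit <- fit_model_clusters(expr, genes = NULL, k = 2, families = "EII",
                            n_init = 2, seed = 1)
  truth <- rep(1:2, each = n)
  expect_equal(mclust::adjustedRandIndex(fit$labels, truth), 1)
})

test_that("K = 1 BIC equals the closed-form Gaussian MLE BIC", {
  set.seed(7)
  expr <- matrix(rnorm(5 * 60), 5, 60,
                 dimnames = list(paste0("G", 1:5), paste0("S", 1:60)))
  fit <- fit_model_clusters(expr, genes = NULL, k = 1, families = "EEE",
                            standardize = FALSE, seed = 1)
  X <- t(expr)
  n <- nrow(X); d <- ncol(X)
  S <- stats::cov(X) * (n - 1) / n              # MLE covariance
  ll <- -n / 2 * (d * log(2 * pi) + determinant(S)$modulus[1] + d)
  bic <- -2 * ll + (d + d * (d + 1) / 2) * log(n)
  expect_equal(fit$bic, bic, tolerance = 1e-6)
})

test_that("EM responsibilities are proper and the log-likelihood ascends", {
  co <- generate_cohort(small_config(seed = 13))
  fit <- fit_model_clusters(co$expression, families = "diagonal", seed = 2)
  expect_equal(rowSums(fit$responsibilities), rep(1, ncol(co$expression)),
               tolerance = 1e-9)
  expect_equal(fit$labels,
               max.col(fit$responsibilities, ties.method = "first"))
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  ari <- mclust::adjustedRandIndex(fit$labels, co$truth$true_cluster)
  expect_gte(ari, 0.85)   # 150-sample cohort; the 405-sample bound is 0.9
})

test_that("panel handling: missing genes warn, too few error", {
  co <- generate_cohort(small_config(seed = 14))
  expr <- co$expression[setdiff(rownames(co$expression), c("WTAP", "FTO")), ]
  expect_warning(fit <- fit_model_clusters(expr, families = "EII",
                                           n_init = 1, seed = 1),
                 "2 panel gene")
  expect_equal(length(fit$genes), 22L)
  tiny <- co$expression[m6a_regulators()$gene[1:5], ]
  expect_error(suppressWarnings(fit_model_clusters(tiny, seed = 1)),
               "panel genes present")
})

test_that("rank-separated groups get lowest / median / highest labels", {
  vals <- data.frame(f = c(1:10, 11:20, 21:30))
  labels <- rep(1:3, each = 10)
  ch <- characterize_clusters(vals, labels)
  expect_equal(ch$label, c("lowest", "median", "highest"))
  expect_lt(ch$kw_p[1], 0.05)
})

test_that("identical groups are all ns with zero KW statistic", {
  vals <- data.frame(f = rep(5, 30))
  ch <- characterize_clusters(vals, rep(1:3, each = 10))
  expect_equal(ch$label, rep("ns", 3))
  expect_equal(ch$kw_stat, rep(0, 3))
  expect_equal(ch$kw_p, rep(1, 3))
})

test_that("KW statistic matches the direct rank formula", {
  groups <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  h <- oracle_kw(groups)
  expect_equal(h, 7.2, tolerance = 1e-12)
  ch <- characterize_clusters(data.frame(f = unlist(groups)),
                              rep(1:3, each = 3))
  expect_equal(ch$kw_stat[1], h, tolerance = 1e-10)
})

test_that("at most one highest and one lowest per feature", {
  set.seed(31)
  for (i in 1:20) {
    vals <- data.frame(f = rnorm(60) + rep(sample(0:2), each = 20))
    ch <- characterize_clusters(vals, rep(1:3, each = 20))
    expect_lte(sum(ch$label == "highest"), 1L)
    expect_lte(sum(ch$label == "lowest"), 1L)
  }
})

test_that("consensus matrix separates well-separated blobs", {
  set.seed(8)
  n <- 15
  expr <- cbind(matrix(rnorm(4 * n, 0, 0.5), 4, n),
                matrix(rnorm(4 * n, 10, 0.5), 4, n))
  dimnames(expr) <- list(paste0("G", 1:4), paste0("S", seq_len(2 * n)))
  cc <- consensus_cluster(expr, k = 2, n_resamples = 50, seed = 2)
  truth <- rep(1:2, each = n)
  same <- outer(truth, truth, `==`)
  off <- upper.tri(cc$consensus)
  expect_true(all(cc$consensus[off & same] == 1))
  expect_true(all(cc$consensus[off & !same] == 0))
  expect_equal(mclust::adjustedRandIndex(cc$labels$cluster, truth), 1)
})

test_that("consensus on exchangeable noise hovers near 0.5", {
  set.seed(9)
  expr <- matrix(rnorm(5 * 60), 5, 60,
                 dimnames = list(paste0("G", 1:5), paste0("S", 1:60)))
  cc <- consensus_cluster(expr, k = 2, n_resamples = 60, seed = 3)
  expect_lt(abs(mean(cc$consensus[upper.tri(cc$consensus)]) - 0.5), 0.1)
})

test_that("consensus matrix is symmetric with unit diagonal", {
  co <- generate_cohort(cohort_config(n_per_cluster = c(15, 15, 15),
                                      n_background = 5, seed = 4))
  cc <- consensus_cluster(co$expression[sprintf("CEG%03d", 1:10), ],
                          k = 3, n_resamples = 20, seed = 5)
  expect_equal(cc$consensus, t(cc$consensus))
  expect_equal(unname(diag(cc$consensus)), rep(1, 45))
})
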