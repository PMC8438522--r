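test_that("projections match the eigendecomposition oracle", {
  set.seed(21)
  for (i in 1:10) {
    g <- sample(3:12, 1); n <- sample(8:25, 1)
    expr <- matrix(rnorm(g * n, 8, 2), g, n,
                   dimnames = list(paste0("g", seq_len(g)),
                                   paste0("s", seq_len(n))))
    sc <- compute_m6ascore(expr)
    or <- oracle_pca_scores(expr)
    # orientation-free comparison: match each component up to sign
    for (j in 1:2) {
      got <- if (j == 1) sc$pc1 else sc$pc2
      ref <- or$proj[, j]
      expect_lt(min(max(abs(got - ref)), max(abs(got + ref))), 1e-8)
    }
    expect_identical(sc$score, sc$pc1 + sc$pc2)  # exact identity
  }
})

test_that("perfectly correlated genes collapse onto one component", {
  expr <- rbind(g1 = c(-1, -1, 1, 1), g2 = c(-1, -1, 1, 1))
  colnames(expr) <- paste0("s", 1:4)
  sc <- compute_m6ascore(expr)
  expect_equal(sc$pc2, rep(0, 4), tolerance = 1e-12)
  expect_equal(sc$score[1], sc$score[2])
  expect_equal(sc$score, -rev(sc$score))       # symmetric about 0
  # orientation rule: positive loadings, so high-expression samples score high
  expect_gt(sc$score[3], 0)
})

test_that("score is invariant to gene and sample ordering", {
  set.seed(22)
  expr <- matrix(rnorm(6 * 12), 6, 12,
                 dimnames = list(paste0("g", 1:6), paste0("s", 1:12)))
  sc <- compute_m6ascore(expr)
  sc_g <- compute_m6ascore(expr[sample(6), ])
  sc_s <- compute_m6ascore(expr[, sample(12)])
  expect_equal(sc$score, sc_g$score, tolerance = 1e-10)
  expect_equal(sc$score,
               sc_s$score[match(sc$sample_id, sc_s$sample_id)],
               tolerance = 1e-10)
})

test_that("duplicated samples get identical scores", {
  set.seed(23)
  expr <- matrix(rnorm(5 * 8), 5, 8,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  dup <- cbind(expr, expr)
  colnames(dup) <- paste0("s", 1:16)
  sc <- compute_m6ascore(dup)
  expect_equal(sc$score[1:8], sc$score[9:16], tolerance = 1e-10)
})

test_that("degenerate inputs error or warn per contract", {
  expr <- matrix(1:8, 2, 4, dimnames = list(c("a", "b"), paste0("s", 1:4)))
  expr["b", ] <- 5                              # zero variance
  expect_warning(expect_error(compute_m6ascore(expr), "insufficient"),
                 "zero-variance")
  one <- matrix(rnorm(4), 1, 4,
                dimnames = list("a", paste0("s", 1:4)))
  expect_error(suppressWarnings(compute_m6ascore(one)), "insufficient")
})

test_that("survival dichotomization agrees with the exhaustive scan", {
  scores <- tibble::tibble(sample_id = paste0("s", 1:6),
                           pc1 = 1:6, pc2 = rep(0, 6),
                           score = c(1, 2, 3, 10, 11, 12))
  clinical <- tibble::tibble(
    sample_id = paste0("s", 1:6),
    pfs_time = c(5, 6, 7, 100, 110, 120),
    pfs_event = c(1L, 1L, 1L, 0L, 0L, 0L))
  out <- dichotomize(scores, clinical, min_group_frac = 0.1)
  # all events sit in the low three scores; the variance-weighted log-rank
  # maximum falls inside that block (cut 2, chi-square 5.63 > 5.05 at cut 3)
  or <- oracle_maxstat(out$score, clinical$pfs_time, clinical$pfs_event)
  expect_equal(unique(out$cutpoint), or$cut)
  expect_equal(unique(out$cutpoint), 2)
  expect_true(all(out$group[out$score <= 2] == "low"))
  expect_true(all(out$group[out$score > 2] == "high"))
  # strictly increasing transform leaves the assignment unchanged
  scores2 <- dplyr::mutate(scores, score = exp(score / 4))
  out2 <- dichotomize(scores2, clinical, min_group_frac = 0.1)
  expect_equal(out2$group, out$group)
})

test_that("identical scores cannot be dichotomized", {
  scores <- tibble::tibble(sample_id = paste0("s", 1:6), pc1 = 0, pc2 = 0,
                           score = rep(1, 6))
  clinical <- tibble::tibble(sample_id = paste0("s", 1:6),
                             pfs_time = 1:6, pfs_event = rep(1L, 6))
  expect_error(dichotomize(scores, clinical), "candidate")
})

test_that("pattern 3 carries the highest score on the synthetic cohort", {
  co <- generate_cohort(small_config(seed = 25))
  ceg <- sprintf("CEG%03d", 1:54)
  sc <- compute_m6ascore(co$expression[ceg, ])
  j <- dplyr::inner_join(sc, co$truth, by = "sample_id")
  means <- tapply(j$score, j$true_cluster, mean)
  expect_true(means[["3"]] > means[["1"]] && means[["1"]] > means[["2"]])
  expect_lt(kruskal.test(j$score, factor(j$true_cluster))$p.value, 0.05)
  # score ordering holds with and without gene standardization
  sc_raw <- compute_m6ascore(co$expression[ceg, ], standardize = FALSE)
  j2 <- dplyr::inner_join(sc_raw, co$truth, by = "sample_id")
  m2 <- tapply(j2$score, j2$true_cluster, mean)
  expect_true(m2[["3"]] > m2[["1"]] && m2[["1"]] > m2[["2"]])
})
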