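test_that("monotone pairs give rho of +1 / -1", {
  x <- c(1, 3, 7, 9, 20)
  expect_equal(spearman_cor(x, x^3)$rho, 1)
  expect_equal(spearman_cor(x, -sqrt(x))$rho, -1)
})

test_that("n = 5 p-values equal full permutation enumeration", {
  set.seed(31)
  for (i in 1:10) {
    x <- sample(100, 5); y <- sample(100, 5)
    got <- spearman_cor(x, y)
    expect_equal(got$method, "exact")
    # independent oracle: stats::cor.test computes the exact null
    # distribution for untied small samples
    ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                     exact = TRUE))
    expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$p_value, min(ref$p.value, 1), tolerance = 1e-10)
  }
})

test_that("degenerate vectors are flagged, not scored", {
  out <- spearman_cor(rep(1, 5), rnorm(5))
  expect_true(is.na(out$rho))
  expect_equal(out$method, "degenerate")
})

test_that("the resampling screen is seed-reproducible", {
  co <- generate_moderator_scenario(small_config(seed = 41))
  sigs <- score_matrix(co$expression,
                       co$gene_sets[co$gene_sets$name == "Th1 cells", ])
  cegs <- c("MSMB", "CEG001", "CEG002")
  a <- run_multicoexp(co$expression, sigs, cegs, regulators = "HNRNPA2B1",
                      n_reps = 30, seed = 5)
  b <- run_multicoexp(co$expression, sigs, cegs, regulators = "HNRNPA2B1",
                      n_reps = 30, seed = 5)
  expect_identical(a, b)
  c <- run_multicoexp(co$expression, sigs, cegs, regulators = "HNRNPA2B1",
                      n_reps = 30, seed = 6)
  expect_false(identical(a$rho, c$rho))
})

test_that("a constant CEG is never reported as a hit", {
  co <- generate_cohort(small_config(seed = 42))
  expr <- rbind(co$expression,
                matrix(3, 1, ncol(co$expression),
                       dimnames = list("FLAT", NULL)))
  sigs <- score_matrix(expr, co$gene_sets)
  cx <- run_multicoexp(expr, sigs, c("FLAT", "CEG001"),
                       regulators = "METTL14", n_reps = 20, seed = 1)
  flat <- cx[cx$ceg == "FLAT", ]
  expect_true(all(is.na(flat$rho)))
})

test_that("the planted moderator is recovered with the right sign", {
  co <- generate_moderator_scenario(small_config(seed = 43))
  sigs <- score_matrix(co$expression,
                       co$gene_sets[co$gene_sets$name == "Th1 cells", ])
  cx <- run_multicoexp(co$expression, sigs, c("MSMB", "CEG001"),
                       regulators = "HNRNPA2B1", seed = 2)
  hit <- cx[cx$ceg == "MSMB", ]
  expect_gt(hit$rho, 0)
  expect_lt(hit$p_value, 0.05)
  # sign flip of the moderation flips the recovered correlation
  co_dn <- generate_moderator_scenario(small_config(seed = 43), sign = -1)
  sig_dn <- score_matrix(co_dn$expression,
                         co_dn$gene_sets[co_dn$gene_sets$name == "Th1 cells", ])
  cx_dn <- run_multicoexp(co_dn$expression, sig_dn, "MSMB",
                          regulators = "HNRNPA2B1", seed = 2)
  expect_lt(cx_dn$rho[cx_dn$ceg == "MSMB"], 0)
})

test_that("monotone transform of a CEG leaves its screen correlation unchanged", {
  # odd subsample size (round(0.6 * 151) = 91) so the median is an order
  # statistic and therefore commutes with monotone transforms
  co <- generate_moderator_scenario(cohort_config(
    n_per_cluster = c(61, 30, 60), n_background = 80, seed = 44))
  sigs <- score_matrix(co$expression,
                       co$gene_sets[co$gene_sets$name == "Th1 cells", ])
  cx1 <- run_multicoexp(co$expression, sigs, "MSMB",
                        regulators = "HNRNPA2B1", n_reps = 40, seed = 3)
  expr2 <- co$expression
  expr2["MSMB", ] <- exp(expr2["MSMB", ] / 2)
  cx2 <- run_multicoexp(expr2, sigs, "MSMB",
                        regulators = "HNRNPA2B1", n_reps = 40, seed = 3)
  expect_equal(cx1$rho, cx2$rho, tolerance = 1e-10)
})

test_that("dropping the relevance filter only adds replicates", {
  co <- generate_moderator_scenario(small_config(seed = 45))
  sigs <- score_matrix(co$expression,
                       co$gene_sets[co$gene_sets$name == "Th1 cells", ])
  filt <- run_multicoexp(co$expression, sigs, "MSMB",
                         regulators = "HNRNPA2B1", n_reps = 50, seed = 4)
  all_r <- run_multicoexp(co$expression, sigs, "MSMB",
                          regulators = "HNRNPA2B1", n_reps = 50, seed = 4,
                          filter_r1 = FALSE)
  expect_gte(all_r$n_valid, filt$n_valid)
  expect_equal(sign(all_r$rho), sign(filt$rho))
})

test_that("median-split contrast recovers the planted interaction direction", {
  co <- generate_moderator_scenario(small_config(seed = 46))
  sigs <- score_matrix(co$expression,
                       co$gene_sets[co$gene_sets$name == "Th1 cells", ])
  ms <- median_split_contrast(co$expression, "HNRNPA2B1", "MSMB", sigs,
                              "Th1 cells")
  expect_equal(nrow(ms), 4L)
  for (lvl in c("high", "low")) {
    sub <- ms[ms$regulator_level == lvl, ]
    expect_gt(sub$mean_score[sub$moderator_level == "high"],
              sub$mean_score[sub$moderator_level == "low"])
  }
  ms2 <- median_split_contrast(co$expression, "HNRNPA2B1", "MSMB", sigs,
                               "Th1 cells")
  expect_identical(ms, ms2)                     # deterministic
})
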