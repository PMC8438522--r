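# three-cluster fixture with deterministic DEG structure: 54 genes shifted
# in every one-vs-rest contrast, 20 in only two, 30 null
deg_fixture <- function(n_per = 30, sd = 0.05, seed = 1) {
  set.seed(seed)
  cl <- rep(1:3, each = n_per)
  n <- length(cl)
  mk <- function(means, m) {
    t(vapply(seq_len(m), function(i) means[cl] + rnorm(n, sd = sd),
             numeric(n)))
  }
  # one-vs-rest pools the two other clusters, so the "rest" variance is the
  # mixture spread; spacings below keep every contrast significant AND above
  # 1 log2 unit for the 54 ALL genes, while TWO genes sit exactly at the
  # rest mean for cluster 2
  expr <- rbind(mk(c(0, 1.5, 9), 54),
                mk(c(0, 1.5, 3), 20),
                mk(c(5, 5, 5), 30))
  rownames(expr) <- c(sprintf("ALL%02d", 1:54), sprintf("TWO%02d", 1:20),
                      sprintf("NULL%02d", 1:30))
  colnames(expr) <- sprintf("S%03d", seq_len(n))
  list(expr = expr, labels = cl)
}
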