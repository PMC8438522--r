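# Dunn's post hoc z statistics on the joint ranks, with tie correction
.dunn_pairs <- function(x, g) {
  N <- length(x)
  r <- rank(x)
  tie_tab <- table(x)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  lev <- levels(g)
  rbar <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  pairs <- combn(lev, 2L)
  z <- vapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ns[[a]] + 1 / ns[[b]]))
    if (se == 0) return(0)
    (rbar[[a]] - rbar[[b]]) / se
  }, 0)
  p <- 2 * pnorm(-abs(z))
  tibble::tibble(cluster_a = pairs[1L, ], cluster_b = pairs[2L, ], z = z,
                 p_adj = p.adjust(p, "holm"))
}

#' Characterize clusters by the highest / median / lowest rule
#'
#' Per feature, a Kruskal-Wallis test across clusters; when it is significant
#' (p < `alpha`), Dunn pairwise z tests (Holm-adjusted) decide the labels: a
#' cluster is `"highest"` when its median exceeds every other cluster's and
#' all of its pairwise comparisons are significant, `"lowest"` symmetrically,
#' and `"median"` when it differs significantly from all others with a median
#' strictly in between; otherwise `"ns"`. At most one cluster per feature can
#' be `"highest"` and at most one `"lowest"`.
#'
#' @param data Data frame or matrix, samples x features (numeric).
#' @param labels Cluster label per sample (any coercible to factor).
#' @param alpha Significance level for both KW and pairwise tests.
#' @return Tibble with `feature`, `cluster`, `median`, `kw_stat`, `kw_p`, `label`;
#'   pairwise Dunn results are attached as attribute `"pairwise"`.
#' @export
characterize_clusters <- function(data, labels, alpha = 0.05) {
  data <- as.data.frame(data)
  g <- factor(labels)
  if (nlevels(g) < 2L || any(table(g) < 2L)) {
    abort("need >= 2 clusters with >= 2 members each")
  }
  lev <- levels(g)
  res <- list(); pw <- list()
  for (f in colnames(data)) {
    x <- data[[f]]
    med <- tapply(x, g, median)
    if (length(unique(x)) == 1L) {
      res[[f]] <- tibble::tibble(feature = f, cluster = lev,
                                 median = as.numeric(med), kw_stat = 0,
                                 kw_p = 1, label = "ns")
      next
    }
    kw <- suppressWarnings(kruskal.test(x, g))
    lab <- rep("ns", length(lev))
    names(lab) <- lev
    if (is.finite(kw$p.value) && kw$p.value < alpha) {
      dp <- .dunn_pairs(x, g)
      pw[[f]] <- mutate(dp, feature = f, .before = 1L)
      sig_vs_all <- vapply(lev, function(cl) {
        rows <- dp$cluster_a == cl | dp$cluster_b == cl
        all(dp$p_adj[rows] < alpha)
      }, TRUE)
      for (cl in lev) {
        others <- med[setdiff(lev, cl)]
        if (!sig_vs_all[[cl]]) next
        if (med[[cl]] > max(others)) lab[cl] <- "highest"
        else if (med[[cl]] < min(others)) lab[cl] <- "lowest"
        else if (med[[cl]] > min(others) && med[[cl]] < max(others)) {
          lab[cl] <- "median"
        }
      }
    }
    res[[f]] <- tibble::tibble(feature = f, cluster = lev,
                               median = as.numeric(med),
                               kw_stat = unname(kw$statistic),
                               kw_p = unname(kw$p.value), label = unname(lab))
  }
  out <- list_rbind(res)
  attr(out, "pairwise") <- if (length(pw)) list_rbind(pw) else NULL
  out
}
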