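#' Construct the per-sample m6Ascore from CEG expression
#'
#' Principal component analysis of the sample x CEG matrix; the score of a
#' sample is the sum of its projections on the first two components. Genes
#' are standardized (zero mean, unit variance) by default. The sign of each
#' component is oriented so that its largest-magnitude gene loading is
#' positive, which makes scores (and the high/low split downstream)
#' reproducible across linear-algebra backends.
#'
#' @param expr Expression matrix (genes x samples) restricted to the CEG set;
#'   needs >= 2 genes and >= 3 samples.
#' @param standardize Standardize genes before PCA (default `TRUE`).
#' @return Tibble with columns `sample_id`, `pc1`, `pc2`, `score`
#'   (`score = pc1 + pc2` exactly). Attributes: `"loadings"` (oriented gene
#'   loadings for PC1/PC2), `"flipped"` (logical length 2, whether each
#'   component was sign-flipped), `"dropped"` (zero-variance genes removed).
#' @export
compute_m6ascore <- function(expr, standardize = TRUE) {
  stopifnot(is.matrix(expr))
  if (ncol(expr) < 3L) abort("need >= 3 samples to compute the m6Ascore")
  v <- apply(expr, 1L, var)
  dropped <- rownames(expr)[v == 0]
  if (length(dropped)) {
    warn(sprintf("dropping %d zero-variance gene(s) before PCA", length(dropped)))
    expr <- expr[v > 0, , drop = FALSE]
  }
  if (nrow(expr) < 2L) abort("insufficient CEGs: need >= 2 genes with variance")
  x <- t(expr)                                  # samples x genes
  x <- scale(x, center = TRUE, scale = standardize)
  pc <- prcomp(x, center = FALSE, scale. = FALSE)
  k <- min(2L, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  flipped <- logical(2)
  for (j in seq_len(k)) {
    top <- which.max(abs(rot[, j]))
    if (rot[top, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
      flipped[j] <- TRUE
    }
  }
  pc1 <- as.numeric(scores[, 1L])
  pc2 <- if (k >= 2L) as.numeric(scores[, 2L]) else rep(0, nrow(scores))
  out <- tibble::tibble(sample_id = colnames(expr), pc1 = pc1, pc2 = pc2,
                        score = pc1 + pc2)
  attr(out, "loadings") <- rot
  attr(out, "flipped") <- flipped
  attr(out, "dropped") <- dropped
  out
}

#' Dichotomize the m6Ascore against survival
#'
#' Splits samples into high- and low-score groups at the cutpoint maximizing
#' the two-group log-rank statistic over all candidate splits
#' ([maxstat_cutpoint()]). The low group is `score <= cutpoint`.
#'
#' @param scores Tibble from [compute_m6ascore()] (needs `sample_id`, `score`).
#' @param clinical Clinical tibble with `sample_id`, `pfs_time`, `pfs_event`.
#' @param min_group_frac Minimum fraction of samples on each side of a
#'   candidate cutpoint (default 0.1).
#' @return `scores` restricted to joined samples, with columns `group`
#'   (`"high"`/`"low"`) and `cutpoint` added; the selected log-rank statistic
#'   is attached as attribute `"maxstat"`. Note the log-rank p computed for
#'   the resulting groups is selection-biased and descriptive only.
#' @export
dichotomize <- function(scores, clinical, min_group_frac = 0.1) {
  joined <- inner_join(scores, clinical, by = "sample_id")
  if (nrow(joined) < 3L) abort("too few samples after score/clinical join")
  if (sum(joined$pfs_event) < 2L) abort("need >= 2 events to select a cutpoint")
  ms <- maxstat_cutpoint(joined$score, joined$pfs_time, joined$pfs_event,
                         min_group_frac = min_group_frac)
  out <- scores[scores$sample_id %in% joined$sample_id, , drop = FALSE]
  out$group <- ifelse(out$score > ms$cutpoint, "high", "low")
  out$cutpoint <- ms$cutpoint
  attr(out, "maxstat") <- ms$statistic
  attr(out, "loadings") <- attr(scores, "loadings")
  out
}
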