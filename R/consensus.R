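#' Monti-style consensus clustering
#'
#' Repeatedly subsamples a fraction of the samples, clusters each subsample
#' into K groups (k-means or average-linkage hierarchical clustering on
#' Euclidean distance), and records for every sample pair how often it
#' co-clusters among the resamples where both were drawn. Final labels come
#' from hierarchical clustering of 1 - consensus. Used to derive the gene
#' clusters that corroborate the regulator patterns.
#'
#' @param expr Expression matrix (genes x samples); samples are clustered.
#' @param k Number of clusters (>= 2).
#' @param n_resamples Number of subsampling iterations (>= 10).
#' @param sample_frac Fraction of samples drawn (without replacement) each
#'   iteration.
#' @param method `"kmeans"` or `"hclust"` for the inner clustering.
#' @param standardize Z-score genes first (default `TRUE`).
#' @param seed Integer seed; the run is deterministic given it.
#' @return Object of class `m6a_consensus`: `consensus` (symmetric matrix
#'   with unit diagonal), `labels` tibble (`sample_id`, `cluster`), `k`,
#'   `n_resamples`. Pairs never co-sampled get consensus 0.5 with a warning.
#' @export
consensus_cluster <- function(expr, k = 3L, n_resamples = 100L,
                              sample_frac = 0.8, method = c("kmeans", "hclust"),
                              standardize = TRUE, seed = 1L) {
  method <- match.arg(method)
  if (k < 2L) abort("k must be >= 2")
  if (n_resamples < 10L) abort("n_resamples must be >= 10")
  n <- ncol(expr)
  X <- t(expr)
  if (standardize) {
    X <- scale(X)
    X <- X[, apply(X, 2L, function(c) all(is.finite(c))), drop = FALSE]
  }
  m <- max(2L * k, round(sample_frac * n))
  set.seed(seed)
  co <- matrix(0, n, n)
  tog <- matrix(0, n, n)
  for (b in seq_len(n_resamples)) {
    idx <- sample.int(n, m)
    cl <- if (method == "kmeans") {
      kmeans(X[idx, , drop = FALSE], centers = k, nstart = 1L,
             iter.max = 50L)$cluster
    } else {
      cutree(hclust(dist(X[idx, , drop = FALSE]), method = "average"), k)
    }
    same <- outer(cl, cl, `==`) * 1
    co[idx, idx] <- co[idx, idx] + same
    tog[idx, idx] <- tog[idx, idx] + 1
  }
  never <- tog == 0 & upper.tri(tog)
  if (any(never)) {
    warn(sprintf("%d sample pair(s) never co-sampled; consensus set to 0.5",
                 sum(never)))
  }
  cons <- ifelse(tog > 0, co / pmax(tog, 1), 0.5)
  diag(cons) <- 1
  cons <- (cons + t(cons)) / 2
  dimnames(cons) <- list(colnames(expr), colnames(expr))
  labels <- cutree(hclust(as.dist(1 - cons), method = "average"), k)
  structure(list(
    consensus = cons,
    labels = tibble::tibble(sample_id = colnames(expr),
                            cluster = unname(labels)),
    k = k, n_resamples = n_resamples, method = method),
    class = "m6a_consensus")
}

#' @export
print.m6a_consensus <- function(x, ...) {
  cat(sprintf("consensus clustering: K = %d over %d resamples (%s)\n",
              x$k, x$n_resamples, x$method))
  cat("cluster sizes:", paste(table(x$labels$cluster), collapse = "/"), "\n")
  invisible(x)
}

#' @exportS3Method generics::glance
glance.m6a_consensus <- function(x, ...) {
  off <- x$consensus[upper.tri(x$consensus)]
  tibble::tibble(k = x$k, n_resamples = x$n_resamples,
                 mean_consensus = mean(off),
                 frac_definite = mean(off < 0.1 | off > 0.9))
}
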