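# ---- Gaussian mixture EM over a small sweep of covariance families -------
#
# Family codes follow the usual volume/shape/orientation shorthand:
#   EII spherical shared, VII spherical per-cluster,
#   EEI diagonal shared, VVI diagonal per-cluster,
#   EEE full shared,     VVV full per-cluster.

.gmm_families <- c("EII", "VII", "EEI", "VVI", "EEE", "VVV")

.expand_families <- function(families) {
  out <- unlist(lapply(families, function(f) {
    switch(f,
           spherical = c("EII", "VII"),
           diagonal = c("EEI", "VVI"),
           full = c("EEE", "VVV"),
           f)
  }))
  bad <- setdiff(out, .gmm_families)
  if (length(bad)) abort(paste0("unknown covariance family: ",
                                paste(bad, collapse = ", ")))
  unique(out)
}

.gmm_npar <- function(family, K, d) {
  cov_par <- switch(family,
                    EII = 1, VII = K, EEI = d, VVI = K * d,
                    EEE = d * (d + 1) / 2, VVV = K * d * (d + 1) / 2)
  K * d + (K - 1) + cov_par
}

# k-means++ style seeding: spread initial centers by squared distance
.kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  centers <- matrix(NA_real_, K, ncol(X))
  centers[1L, ] <- X[sample.int(n, 1L), ]
  if (K > 1L) {
    d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
    for (k in 2:K) {
      probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[k, ] <- X[sample.int(n, 1L, prob = probs), ]
      d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[k, ])^2))
    }
  }
  centers
}

# per-cluster log Gaussian density under the family's covariance structure
.gmm_logdens <- function(X, mu, covs, family) {
  n <- nrow(X); d <- ncol(X); K <- nrow(mu)
  ld <- matrix(NA_real_, n, K)
  for (k in seq_len(K)) {
    xc <- sweep(X, 2L, mu[k, ])
    if (family %in% c("EII", "VII")) {
      s2 <- covs[[k]]
      ld[, k] <- -0.5 * (d * log(2 * pi * s2) + rowSums(xc^2) / s2)
    } else if (family %in% c("EEI", "VVI")) {
      v <- covs[[k]]
      ld[, k] <- -0.5 * (sum(log(2 * pi * v)) +
                           rowSums(sweep(xc^2, 2L, v, "/")))
    } else {
      R <- covs[[k]]                           # cholesky factor of Sigma
      y <- backsolve(R, t(xc), transpose = TRUE)
      ld[, k] <- -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(R))) +
                           colSums(y^2))
    }
  }
  ld
}

.gmm_mstep_cov <- function(X, resp, mu, family, ridge = 1e-6) {
  n <- nrow(X); d <- ncol(X); K <- ncol(resp)
  nk <- colSums(resp)
  if (family == "EII") {
    s2 <- sum(vapply(seq_len(K), function(k) {
      sum(resp[, k] * rowSums(sweep(X, 2L, mu[k, ])^2))
    }, 0)) / (n * d)
    rep(list(max(s2, ridge)), K)
  } else if (family == "VII") {
    lapply(seq_len(K), function(k) {
      max(sum(resp[, k] * rowSums(sweep(X, 2L, mu[k, ])^2)) / (nk[k] * d),
          ridge)
    })
  } else if (family == "EEI") {
    v <- Reduce(`+`, lapply(seq_len(K), function(k) {
      colSums(resp[, k] * sweep(X, 2L, mu[k, ])^2)
    })) / n
    rep(list(pmax(v, ridge)), K)
  } else if (family == "VVI") {
    lapply(seq_len(K), function(k) {
      pmax(colSums(resp[, k] * sweep(X, 2L, mu[k, ])^2) / nk[k], ridge)
    })
  } else if (family == "EEE") {
    S <- Reduce(`+`, lapply(seq_len(K), function(k) {
      xc <- sweep(X, 2L, mu[k, ])
      crossprod(xc * resp[, k], xc)
    })) / n
    rep(list(chol(S + diag(ridge, d))), K)
  } else {
    lapply(seq_len(K), function(k) {
      xc <- sweep(X, 2L, mu[k, ])
      chol(crossprod(xc * resp[, k], xc) / nk[k] + diag(ridge, d))
    })
  }
}

# one EM run from hard initial labels (or a responsibility matrix, to
# resume a short run); returns NULL on degeneracy
.gmm_em <- function(X, K, family, init_labels, max_iter = 200, tol = 1e-6,
                    ridge = 1e-6) {
  n <- nrow(X)
  if (is.matrix(init_labels)) {
    resp <- init_labels
  } else {
    resp <- matrix(0, n, K)
    resp[cbind(seq_len(n), init_labels)] <- 1
  }
  loglik_trace <- numeric(0)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    nk <- colSums(resp)
    if (any(nk < 2)) return(NULL)              # degenerate cluster
    wts <- nk / n
    mu <- crossprod(resp, X) / nk
    covs <- .gmm_mstep_cov(X, resp, mu, family, ridge)
    ld <- sweep(.gmm_logdens(X, mu, covs, family), 2L, log(wts), "+")
    m <- apply(ld, 1L, max)
    lse <- m + log(rowSums(exp(ld - m)))
    ll <- sum(lse)
    resp <- exp(ld - lse)
    loglik_trace <- c(loglik_trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) break
    ll_old <- ll
  }
  nk <- colSums(resp)
  if (any(nk < 2)) return(NULL)
  list(weights = nk / n, means = mu, covs = covs, resp = resp,
       loglik = ll, loglik_trace = loglik_trace, n_iter = iter)
}

#' Model-based clustering of the m6A regulator panel
#'
#' Identifies m6A regulation patterns by fitting Gaussian mixture models to
#' the (standardized) regulator expression with EM, sweeping a compact set of
#' covariance families and selecting the fit with the best (smallest)
#' `BIC = -2 loglik + npar log(n)`. EM restarts from k-means++-style seeds;
#' everything is deterministic given `seed`.
#'
#' @param expr Expression matrix (genes x samples).
#' @param genes Optional gene subset (default: the 24-regulator panel).
#'   Missing genes are reported; the run proceeds with a warning if at least
#'   `min_genes` are present.
#' @param k Number of clusters (default 3, the three-pattern design).
#' @param families Covariance families: any of `"spherical"`, `"diagonal"`,
#'   `"full"` (each expanding to a shared and a per-cluster variant) or the
#'   explicit codes `EII/VII/EEI/VVI/EEE/VVV`.
#' @param standardize Z-score each gene before clustering (default `TRUE`).
#' @param n_init Short exploratory EM runs per family (emEM strategy: each
#'   runs 15 iterations from a k-means++ seed; the two best continue to
#'   convergence alongside two deterministic k-means / Ward starts).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @param max_restarts Extra restarts allowed when a cluster collapses below
#'   2 members before erroring.
#' @param min_genes Minimum panel genes required to proceed.
#' @param seed Integer seed.
#' @return Object of class `m6a_gmm`: `labels` (argmax responsibility, ties
#'   to the lowest cluster index), `K`, `responsibilities`, `loglik`,
#'   `loglik_trace`, `bic`, `family`, `bic_table`, `means`, `sample_ids`.
#' @export
fit_model_clusters <- function(expr, genes = m6a_regulators()$gene, k = 3L,
                               families = c("spherical", "diagonal", "full"),
                               standardize = TRUE, n_init = 6L,
                               max_iter = 200L, tol = 1e-6, max_restarts = 5L,
                               min_genes = 16L, seed = 1L) {
  if (!is.null(genes)) {
    present <- intersect(genes, rownames(expr))
    missing <- setdiff(genes, rownames(expr))
    if (length(missing)) {
      if (length(present) < min_genes) {
        abort(sprintf("only %d of %d panel genes present (need >= %d)",
                      length(present), length(genes), min_genes))
      }
      warn(sprintf("%d panel gene(s) missing, proceeding with %d: %s",
                   length(missing), length(present),
                   paste(head(missing, 5L), collapse = ", ")))
    }
    expr <- expr[present, , drop = FALSE]
  }
  n <- ncol(expr)
  if (n < k * 5L) abort(sprintf("need >= %d samples for K = %d", k * 5L, k))
  X <- t(expr)
  if (standardize) X <- scale(X)
  X <- X[, apply(X, 2L, function(c) all(is.finite(c))), drop = FALSE]
  fams <- .expand_families(families)
  set.seed(seed)

  # two deterministic starts (k-means with restarts; Ward agglomeration,
  # the classic model-based-clustering initialization) plus k-means++
  # seeded hard assignments for the remaining ones
  det_inits <- if (k > 1L) {
    list(kmeans(X, centers = k, nstart = 10L, iter.max = 50L)$cluster,
         cutree(hclust(dist(X), method = "ward.D2"), k))
  } else {
    list(rep(1L, nrow(X)))
  }

  fits <- list()
  for (fam in fams) {
    best <- NULL
    # deterministic starts run to convergence
    for (init in det_inits) {
      if (length(unique(init)) < k) next
      fit <- .gmm_em(X, k, fam, init, max_iter, tol)
      if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) {
        best <- fit
      }
    }
    # emEM: many short runs from k-means++ seeds, best one continued
    shorts <- list()
    tries <- 0L
    while (length(shorts) < n_init && tries < n_init + max_restarts) {
      tries <- tries + 1L
      centers <- .kmeanspp_centers(X, k)
      d2 <- vapply(seq_len(k), function(j) {
        rowSums(sweep(X, 2L, centers[j, ])^2)
      }, numeric(nrow(X)))
      init <- max.col(-d2, ties.method = "first")
      if (length(unique(init)) < k) next
      sfit <- .gmm_em(X, k, fam, init, max_iter = 15L, tol)
      if (!is.null(sfit)) shorts[[length(shorts) + 1L]] <- sfit
    }
    if (length(shorts)) {
      lls <- vapply(shorts, `[[`, 0, "loglik")
      for (j in order(lls, decreasing = TRUE)[seq_len(min(2L,
                                                          length(shorts)))]) {
        fit <- .gmm_em(X, k, fam, shorts[[j]]$resp, max_iter, tol)
        if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) {
          best <- fit
        }
      }
    }
    if (is.null(best)) {
      abort(sprintf("EM degenerate for family %s after %d restarts", fam,
                    max_restarts))
    }
    fits[[fam]] <- best
  }

  # cross-family warm starts: a basin found under one covariance structure
  # often dominates under another, so re-run each family's EM from every
  # other family's converged responsibilities and keep the best likelihood
  if (length(fams) > 1L) {
    resp_pool <- lapply(fits, `[[`, "resp")
    for (fam in fams) {
      for (other in setdiff(fams, fam)) {
        refit <- .gmm_em(X, k, fam, resp_pool[[other]], max_iter, tol)
        if (!is.null(refit) && refit$loglik > fits[[fam]]$loglik) {
          fits[[fam]] <- refit
        }
      }
    }
  }
  for (fam in fams) {
    fits[[fam]]$family <- fam
    fits[[fam]]$bic <- -2 * fits[[fam]]$loglik +
      .gmm_npar(fam, k, ncol(X)) * log(n)
  }
  bic_table <- tibble::tibble(
    family = names(fits),
    loglik = map_dbl(fits, "loglik"),
    npar = vapply(names(fits), .gmm_npar, 0, K = k, d = ncol(X)),
    bic = map_dbl(fits, "bic")) |> arrange(.data$bic)
  sel <- fits[[bic_table$family[1L]]]
  labels <- max.col(sel$resp, ties.method = "first")
  structure(list(
    labels = labels, K = k, responsibilities = sel$resp,
    loglik = sel$loglik, loglik_trace = sel$loglik_trace, bic = sel$bic,
    family = sel$family, bic_table = bic_table, means = sel$means,
    weights = sel$weights, n_iter = sel$n_iter, genes = colnames(X),
    sample_ids = colnames(expr), seed = seed),
    class = "m6a_gmm")
}

#' @export
print.m6a_gmm <- function(x, ...) {
  cat(sprintf("Gaussian mixture regulation patterns: K = %d, family %s, BIC %.1f\n",
              x$K, x$family, x$bic))
  cat("cluster sizes:", paste(tabulate(x$labels, x$K), collapse = "/"), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.m6a_gmm <- function(x, ...) {
  as_tibble(x$means, .name_repair = "minimal") |>
    setNames(x$genes) |>
    mutate(cluster = seq_len(x$K),
           size = tabulate(x$labels, x$K), .before = 1L) |>
    tidyr::pivot_longer(-c("cluster", "size"), names_to = "gene",
                        values_to = "mean")
}

#' @exportS3Method generics::glance
glance.m6a_gmm <- function(x, ...) {
  tibble::tibble(K = x$K, family = x$family, loglik = x$loglik, bic = x$bic,
                 n_iter = x$n_iter, n = length(x$labels))
}

#' Per-sample cluster assignment as a tibble
#'
#' @param fit An `m6a_gmm` object.
#' @return Tibble with `sample_id` and `cluster`.
#' @export
cluster_labels <- function(fit) {
  tibble::tibble(sample_id = fit$sample_ids, cluster = fit$labels)
}
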