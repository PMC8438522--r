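# ---- empirical-Bayes moderated t, one cluster vs rest ---------------------

# invert the trigamma function by Newton iteration (for the prior df fit)
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

# moment-match the scaled-F prior of gene variances on the log scale:
# log s^2 ~ log s0^2 + log F(d, d0); returns prior df d0 and prior var s02
.fit_variance_prior <- function(s2, d) {
  ok <- s2 > 0
  if (!any(ok)) return(list(d0 = 0, s02 = 0))
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  ev <- mean(e)
  vz <- sum((e - ev)^2) / (length(e) - 1) - trigamma(d / 2)
  if (!is.finite(vz) || vz <= 0) {
    return(list(d0 = Inf, s02 = exp(ev)))
  }
  d0 <- 2 * .trigamma_inverse(vz)
  s02 <- exp(ev + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

#' Differentially expressed genes of one regulation pattern versus the rest
#'
#' One-vs-rest moderated t-test per gene on log2 expression: ordinary
#' two-sample statistics with the gene-wise variances shrunk toward a common
#' prior by empirical Bayes (posterior
#' `s2_tilde = (d0 s0^2 + d s^2) / (d0 + d)`, with the prior df `d0` and
#' prior variance `s0^2` moment-matched across genes on the log-variance
#' scale). A gene passes when `p < p_threshold` and the linear fold change
#' exceeds `fc_threshold` (fold change 2 means `|log2 FC| > 1`).
#'
#' @param expr Expression matrix (genes x samples), log2 scale.
#' @param labels Cluster label per sample (aligned with columns).
#' @param cluster_id The cluster screened against the rest.
#' @param p_threshold,fc_threshold The passing rule (defaults 0.05 and 2).
#' @param moderated Use empirical-Bayes shrinkage (default `TRUE`); with
#'   `FALSE`, or when every gene has zero within-group variance, the ordinary
#'   pooled t-test is used.
#' @return Tibble: `gene_id`, `log2_fc` (cluster minus rest), `t`, `df`,
#'   `p_value`, `passes`.
#' @export
cluster_degs <- function(expr, labels, cluster_id, p_threshold = 0.05,
                         fc_threshold = 2, moderated = TRUE) {
  stopifnot(ncol(expr) == length(labels))
  in_cl <- labels == cluster_id
  n1 <- sum(in_cl); n2 <- sum(!in_cl)
  if (n1 < 3L || n2 < 3L) abort("cluster and rest each need >= 3 samples")
  x1 <- expr[, in_cl, drop = FALSE]
  x2 <- expr[, !in_cl, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2); ss2 <- rowSums((x2 - m2)^2)
  d <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / d
  lfc <- m1 - m2
  scale_fac <- sqrt(1 / n1 + 1 / n2)
  if (moderated && any(s2 > 0)) {
    prior <- .fit_variance_prior(s2, d)
    if (prior$s02 == 0 && prior$d0 == 0) {
      warn("all gene variances are zero; falling back to the ordinary t-test")
      s2_tilde <- s2; df_total <- rep(d, length(s2))
    } else if (is.infinite(prior$d0)) {
      s2_tilde <- rep(prior$s02, length(s2)); df_total <- rep(Inf, length(s2))
    } else {
      s2_tilde <- (prior$d0 * prior$s02 + d * s2) / (prior$d0 + d)
      df_total <- rep(prior$d0 + d, length(s2))
    }
  } else {
    if (!any(s2 > 0)) warn("all gene variances are zero; t statistics undefined where variance is 0")
    s2_tilde <- s2; df_total <- rep(d, length(s2))
  }
  tt <- lfc / (sqrt(s2_tilde) * scale_fac)
  p <- 2 * pt(-abs(tt), df_total)
  p[!is.finite(tt)] <- ifelse(lfc[!is.finite(tt)] == 0, 1, 0)
  tibble::tibble(
    gene_id = rownames(expr), log2_fc = unname(lfc), t = unname(tt),
    df = unname(df_total), p_value = unname(p),
    passes = unname(p < p_threshold & abs(lfc) > log2(fc_threshold)))
}

#' Intersect per-cluster DEG lists into the CEG set
#'
#' The co-expressed genes (CEGs) are the genes differentially expressed in
#' every regulation pattern: the intersection of the per-cluster passing
#' sets.
#'
#' @param deg_lists List (>= 2) of tibbles from [cluster_degs()].
#' @return List of class `ceg_set`: `members` (character), `per_cluster`
#'   (named integer vector of passing counts). Empty intersection is valid
#'   but warned about.
#' @export
intersect_cegs <- function(deg_lists) {
  if (length(deg_lists) < 2L) abort("need >= 2 DEG lists to intersect")
  passing <- lapply(deg_lists, function(d) d$gene_id[d$passes])
  members <- Reduce(intersect, passing)
  if (!length(members)) warn("empty CEG set: no gene passes in every cluster")
  nm <- names(deg_lists) %||% paste0("cluster", seq_along(deg_lists))
  structure(list(members = members,
                 per_cluster = setNames(lengths(passing), nm)),
            class = "ceg_set")
}

#' @export
print.ceg_set <- function(x, ...) {
  cat(sprintf("CEG set: %d genes (per-cluster DEG counts: %s)\n",
              length(x$members),
              paste(names(x$per_cluster), x$per_cluster, sep = "=",
                    collapse = ", ")))
  invisible(x)
}
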