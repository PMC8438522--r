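# Independent oracle implementations used to cross-check the package.
# Each is written as a direct, brute-force transcription of the definition,
# sharing no code with the implementation it checks.

# ssGSEA: explicit position-by-position running sum
oracle_ssgsea <- function(profile, set, alpha) {
  nm <- names(profile)
  ord <- order(-profile, nm)
  ranked <- nm[ord]
  N <- length(ranked)
  in_set <- ranked %in% set
  n_in <- sum(in_set)
  denom_in <- 0
  for (i in seq_len(N)) if (in_set[i]) denom_in <- denom_in + (N - i + 1)^alpha
  es <- 0; cum_in <- 0; cum_out <- 0
  for (i in seq_len(N)) {
    if (in_set[i]) cum_in <- cum_in + (N - i + 1)^alpha else cum_out <- cum_out + 1
    es <- es + cum_in / denom_in - cum_out / (N - n_in)
  }
  es
}

# Kaplan-Meier: explicit product over risk sets
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ut))
  for (i in seq_along(ut)) {
    d <- sum(time == ut[i] & event == 1)
    r <- sum(time >= ut[i])
    s <- s * (1 - d / r)
    surv[i] <- s
  }
  data.frame(time = ut, surv = surv)
}

# two-group log-rank: explicit O-E / V sums over event times
oracle_logrank2 <- function(time, event, group) {
  g1 <- group == sort(unique(group))[1]
  ut <- sort(unique(time[event == 1]))
  o1 <- 0; e1 <- 0; v <- 0
  for (t in ut) {
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    n <- sum(time >= t)
    n1 <- sum(time >= t & g1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (v <= 0) return(0)
  (o1 - e1)^2 / v
}

# exhaustive cutpoint scan scoring each split with survival::survdiff
oracle_maxstat <- function(score, time, event, min_group_frac = 0.1) {
  n <- length(score)
  min_size <- ceiling(min_group_frac * n)
  cands <- sort(unique(score))
  best <- NULL
  for (c in cands) {
    low <- score <= c
    if (sum(low) < min_size || sum(!low) < min_size) next
    st <- survival::survdiff(survival::Surv(time, event) ~ low)$chisq
    if (is.null(best) || st > best$stat + 1e-12) best <- list(cut = c, stat = st)
  }
  best
}

# PCA projections from a brute-force eigendecomposition of the covariance
oracle_pca_scores <- function(expr, standardize = TRUE) {
  x <- scale(t(expr), center = TRUE, scale = standardize)
  ev <- eigen(stats::cov(x), symmetric = TRUE)
  proj <- x %*% ev$vectors[, 1:2]
  list(proj = proj, vectors = ev$vectors[, 1:2])
}

# AUC by counting all positive-negative pairs with half-weight ties
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# DeLong structural components by direct double loops
oracle_delong_components <- function(scores, labels) {
  pos <- which(as.logical(labels)); neg <- which(!as.logical(labels))
  v10 <- vapply(pos, function(i) {
    mean(vapply(neg, function(j) {
      if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0
    }, 0))
  }, 0)
  v01 <- vapply(neg, function(j) {
    mean(vapply(pos, function(i) {
      if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0
    }, 0))
  }, 0)
  list(v10 = v10, v01 = v01)
}

# Breslow partial log-likelihood, maximized by golden-section search
oracle_cox_beta <- function(time, event, x) {
  pll <- function(beta) {
    ll <- 0
    for (t in sort(unique(time[event == 1]))) {
      dead <- which(time == t & event == 1)
      risk <- which(time >= t)
      ll <- ll + sum(beta * x[dead]) -
        length(dead) * log(sum(exp(beta * x[risk])))
    }
    ll
  }
  stats::optimize(pll, c(-8, 8), maximum = TRUE, tol = 1e-8)$maximum
}

# Kruskal-Wallis H by the direct rank formula (no tie correction needed for
# distinct values)
oracle_kw <- function(groups) {
  x <- unlist(groups)
  N <- length(x)
  r <- rank(x)
  idx <- rep(seq_along(groups), lengths(groups))
  rbar <- tapply(r, idx, mean)
  12 / (N * (N + 1)) *
    sum(lengths(groups) * (rbar - (N + 1) / 2)^2)
}

# a compact survival fixture: n samples, exponential times, binomial events
random_surv_fixture <- function(n, seed) {
  set.seed(seed)
  list(score = rnorm(n),
       time = round(rexp(n, 0.01), 2) + 0.01,
       event = rbinom(n, 1, 0.7))
}

# small cohort config used across tests (keeps runtimes low)
small_config <- function(seed = 1, ...) {
  cohort_config(n_per_cluster = c(60, 30, 60), n_background = 80,
                seed = seed, ...)
}
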