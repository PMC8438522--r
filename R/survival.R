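#' Kaplan-Meier product-limit estimate
#'
#' Thin tidy wrapper around [survival::survfit()]; right censoring handled,
#' the curve starts at S(0) = 1 and is non-increasing.
#'
#' @param data Data frame with survival columns.
#' @param time_col,event_col Column names for follow-up time (days) and the
#'   0/1 event flag.
#' @param group_col Optional column name; one curve per group.
#' @return Tibble with `time`, `n_risk`, `n_event`, `n_censor`, `survival`
#'   (and `group` when grouped), including the time-0 row.
#' @export
km_estimate <- function(data, time_col = "pfs_time", event_col = "pfs_event",
                        group_col = NULL) {
  stopifnot(nrow(data) >= 1L)
  surv <- survival::Surv(data[[time_col]], data[[event_col]])
  if (is.null(group_col)) {
    fit <- survival::survfit(surv ~ 1)
    strata <- rep("all", length(fit$time))
  } else {
    g <- factor(data[[group_col]])
    fit <- survival::survfit(surv ~ g)
    strata <- if (is.null(fit$strata)) rep(levels(g)[1L], length(fit$time)) else
      rep(sub("^g=", "", names(fit$strata)), fit$strata)
  }
  out <- tibble::tibble(group = strata, time = fit$time, n_risk = fit$n.risk,
                        n_event = fit$n.event, n_censor = fit$n.censor,
                        survival = fit$surv)
  zero <- out |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(time = 0, n_risk = max(.data$n_risk), n_event = 0,
                     n_censor = 0, survival = 1, .groups = "drop")
  out <- bind_rows(zero, out) |> arrange(.data$group, .data$time)
  if (is.null(group_col)) out$group <- NULL
  out
}

#' Log-rank test across groups
#'
#' Standard observed-minus-expected statistic with hypergeometric variance,
#' df = number of groups - 1, via [survival::survdiff()].
#'
#' @inheritParams km_estimate
#' @param group_col Column defining >= 2 groups.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `n`, `n_event`.
#' @export
logrank_test <- function(data, group_col = "group", time_col = "pfs_time",
                         event_col = "pfs_event") {
  g <- factor(data[[group_col]])
  if (nlevels(g) < 2L) abort("log-rank test needs >= 2 groups")
  if (sum(data[[event_col]]) < 1L) {
    warn("no events: log-rank statistic is 0, p = 1")
    return(tibble::tibble(statistic = 0, df = nlevels(g) - 1L, p_value = 1,
                          n = nrow(data), n_event = 0L))
  }
  sd <- survival::survdiff(
    survival::Surv(data[[time_col]], data[[event_col]]) ~ g)
  df <- nlevels(g) - 1L
  tibble::tibble(statistic = unname(sd$chisq), df = df,
                 p_value = pchisq(sd$chisq, df, lower.tail = FALSE),
                 n = nrow(data), n_event = as.integer(sum(data[[event_col]])))
}

#' Univariate Cox proportional-hazards regression
#'
#' Fits a single continuous (or binary) covariate by partial likelihood with
#' Breslow tie handling; Wald confidence interval and p-value. Possible
#' monotone partial likelihood (perfect separation) is flagged rather than
#' reported as a converged fit.
#'
#' @inheritParams km_estimate
#' @param covariate_col Column name of the covariate.
#' @return One-row tibble: `term`, `beta`, `hr`, `ci_low`, `ci_high`, `se`,
#'   `p_value`, `converged`, `n`, `n_event`.
#' @export
univariate_cox <- function(data, covariate_col, time_col = "pfs_time",
                           event_col = "pfs_event") {
  x <- data[[covariate_col]]
  if (is.null(x)) abort(sprintf("no column '%s'", covariate_col))
  if (length(unique(x)) < 2L) abort("covariate is constant")
  if (sum(data[[event_col]]) < 2L) abort("need >= 2 events")
  df <- data.frame(time = data[[time_col]], event = data[[event_col]], x = x)
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ x, data = df,
                    ties = "breslow"),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(fit$coefficients)
  se <- sqrt(unname(diag(fit$var)))
  converged <- is.finite(beta) && is.finite(se) && !warned &&
    abs(beta) < 15 && se < 100
  z <- beta / se
  tibble::tibble(
    term = covariate_col, beta = beta, hr = exp(beta),
    ci_low = exp(beta - qnorm(0.975) * se),
    ci_high = exp(beta + qnorm(0.975) * se),
    se = se, p_value = 2 * pnorm(-abs(z)), converged = converged,
    n = fit$n, n_event = as.integer(fit$nevent))
}

# precompute the time structure of the two-group log-rank statistic:
# everything that does not depend on the group indicator
.logrank_prep <- function(time, event) {
  ord <- order(time)
  ts <- time[ord]
  es <- as.numeric(event[ord])
  fac <- factor(ts, levels = unique(ts))
  idx <- which(!duplicated(ts))                # first row of each unique time
  d <- as.numeric(rowsum(es, fac))             # events per unique time
  n_at <- length(ts) - idx + 1                 # at risk per unique time
  keep <- d > 0
  list(ord = ord, fac = fac, idx = idx, es = es, d = d[keep],
       n_at = n_at[keep], keep = keep, n = length(ts))
}

# two-group log-rank chi-square for a logical group vector already permuted
# into the prep's time order
.logrank_chisq <- function(prep, g_sorted) {
  g <- as.numeric(g_sorted)
  n1_at <- rev(cumsum(rev(g)))[prep$idx][prep$keep]
  d1 <- as.numeric(rowsum(g * prep$es, prep$fac))[prep$keep]
  o1 <- sum(d1)
  e1 <- sum(prep$d * n1_at / prep$n_at)
  vterm <- ifelse(prep$n_at > 1,
                  prep$d * (n1_at / prep$n_at) * (1 - n1_at / prep$n_at) *
                    (prep$n_at - prep$d) / (prep$n_at - 1), 0)
  v <- sum(vterm)
  if (v <= 0) return(0)
  (o1 - e1)^2 / v
}

#' Maximally selected log-rank cutpoint
#'
#' Exhaustively evaluates the two-group log-rank statistic at every candidate
#' split of a continuous score (low group = score <= cutpoint) and returns
#' the cutpoint maximizing it. Candidates must leave at least
#' `ceiling(min_group_frac * n)` samples on each side; ties in the maximal
#' statistic are broken toward the smaller cutpoint. The log-rank p for the
#' selected split is selection-biased and reported as descriptive only.
#'
#' @param score Numeric marker values.
#' @param time,event Survival time and 0/1 event flag.
#' @param min_group_frac Minimum group-size fraction (default 0.1).
#' @return List of class `m6a_maxstat`: `cutpoint`, `statistic`,
#'   `p_descriptive`, `groups` (character `"high"`/`"low"` per sample),
#'   `candidates` (tibble of every candidate and its statistic).
#' @export
maxstat_cutpoint <- function(score, time, event, min_group_frac = 0.1) {
  stopifnot(length(score) == length(time), length(time) == length(event))
  n <- length(score)
  if (length(unique(score)) < 2L) abort("no candidate cutpoints: all scores identical")
  if (sum(event) < 2L) abort("need >= 2 events")
  min_size <- ceiling(min_group_frac * n)
  cand <- sort(unique(score))
  n_low <- vapply(cand, function(c) sum(score <= c), 0L)
  ok <- n_low >= min_size & (n - n_low) >= min_size
  cand <- cand[ok]
  if (!length(cand)) abort("no candidate cutpoint respects min_group_frac")
  prep <- .logrank_prep(time, event)
  score_sorted <- score[prep$ord]
  stat <- vapply(cand, function(c) .logrank_chisq(prep, score_sorted <= c), 0)
  best <- which.max(stat)                      # first max = smaller cutpoint
  cut <- cand[best]
  structure(list(
    cutpoint = cut, statistic = stat[best],
    p_descriptive = pchisq(stat[best], 1L, lower.tail = FALSE),
    groups = ifelse(score > cut, "high", "low"),
    candidates = tibble::tibble(cutpoint = cand, statistic = stat)),
    class = "m6a_maxstat")
}

#' @export
print.m6a_maxstat <- function(x, ...) {
  cat(sprintf("maximally selected log-rank cutpoint: %.4g (chi-square %.3f, descriptive p %.3g)\n",
              x$cutpoint, x$statistic, x$p_descriptive))
  cat("groups:", paste(names(table(x$groups)), table(x$groups),
                       sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.m6a_maxstat <- function(x, ...) {
  x$candidates
}

#' @exportS3Method generics::glance
glance.m6a_maxstat <- function(x, ...) {
  tibble::tibble(cutpoint = x$cutpoint, statistic = x$statistic,
                 p_descriptive = x$p_descriptive,
                 n_low = sum(x$groups == "low"),
                 n_high = sum(x$groups == "high"))
}
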