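#' Contingency-table association test
#'
#' Chi-square with `df = (r-1)(c-1)` (no continuity correction, so the
#' statistic is the textbook one and transpose-invariant) or Fisher's exact
#' test for 2x2 tables; `"auto"` picks Fisher for a 2x2 table with any
#' expected count below 5, chi-square otherwise. The two-sided Fisher p sums
#' the probabilities of all tables at most as probable as the observed one.
#'
#' @param table Matrix/table of non-negative counts, >= 2 rows and columns.
#' @param method `"auto"`, `"chi2"` or `"fisher2x2"`.
#' @return One-row tibble: `method`, `statistic` (chi-square; `NA` for
#'   Fisher), `df`, `odds_ratio` (2x2 Fisher only), `p_value`.
#' @export
contingency_test <- function(table, method = c("auto", "chi2", "fisher2x2")) {
  method <- match.arg(method)
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab))) abort("counts must be non-negative integers")
  if (nrow(tab) < 2L || ncol(tab) < 2L) abort("need >= 2 rows and >= 2 columns")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("zero row or column margin")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (method == "auto") {
    method <- if (all(dim(tab) == 2L) && any(expected < 5)) "fisher2x2" else "chi2"
  }
  if (method == "fisher2x2") {
    if (!all(dim(tab) == 2L)) abort("fisher2x2 requires a 2x2 table")
    ft <- fisher.test(tab)
    tibble::tibble(method = "fisher", statistic = NA_real_, df = NA_integer_,
                   odds_ratio = unname(ft$estimate), p_value = ft$p.value)
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    tibble::tibble(method = "chi2", statistic = unname(ct$statistic),
                   df = as.integer(ct$parameter), odds_ratio = NA_real_,
                   p_value = unname(ct$p.value))
  }
}

# DeLong structural components: per positive the mean of the Mann-Whitney
# kernel over negatives (V10) and vice versa (V01)
.delong_components <- function(scores, positive) {
  x <- scores[positive]
  y <- scores[!positive]
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' ROC curve and AUC for a continuous score
#'
#' AUC by the trapezoid over the empirical ROC, which equals the
#' Mann-Whitney probability with half-weight ties; the confidence interval
#' uses the DeLong variance (on the logit scale when the AUC is within 0.1
#' of 0 or 1, so the interval stays inside \[0, 1\]).
#' `positive_direction = "lower"` scores markers whose low values predict
#' the positive class directly.
#'
#' @param scores Numeric marker values.
#' @param labels Positive-class indicator (logical or 0/1).
#' @param positive_direction `"higher"` (default) or `"lower"`.
#' @return Object of class `m6a_roc`: `auc`, `ci95`, `curve` (tibble of
#'   `fpr`, `tpr` from (0,0) to (1,1)), `n_pos`, `n_neg`, `direction`.
#' @export
roc_auc <- function(scores, labels, positive_direction = c("higher", "lower")) {
  positive_direction <- match.arg(positive_direction)
  pos <- as.logical(labels)
  if (!any(pos) || all(pos)) abort("both classes must be present")
  s <- if (positive_direction == "lower") -scores else scores
  comp <- .delong_components(s, pos)
  auc <- comp$auc
  m <- sum(pos); n <- sum(!pos)
  v <- var(comp$v10) / m + var(comp$v01) / n
  se <- sqrt(max(v, 0))
  if (auc > 0.9 || auc < 0.1) {
    if (auc %in% c(0, 1) || se == 0) {
      ci <- c(auc, auc)
    } else {
      lg <- qlogis(auc)
      se_lg <- se / (auc * (1 - auc))
      ci <- plogis(lg + c(-1, 1) * qnorm(0.975) * se_lg)
    }
  } else {
    ci <- pmin(pmax(auc + c(-1, 1) * qnorm(0.975) * se, 0), 1)
  }
  ord <- order(-s)
  brk <- !duplicated(s[ord])                   # threshold at each unique value
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  keep <- c(which(brk)[-1L] - 1L, length(s))   # last index of each tie block
  curve <- tibble::tibble(fpr = c(0, fp[keep] / n), tpr = c(0, tp[keep] / m))
  structure(list(auc = auc, ci95 = ci, se = se, curve = curve, n_pos = m,
                 n_neg = n, direction = positive_direction),
            class = "m6a_roc")
}

#' @export
print.m6a_roc <- function(x, ...) {
  cat(sprintf("AUC = %.3f (95%% CI %.3f-%.3f), %d positive / %d negative, direction: %s\n",
              x$auc, x$ci95[1], x$ci95[2], x$n_pos, x$n_neg, x$direction))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.m6a_roc <- function(x, ...) x$curve

#' @exportS3Method generics::glance
glance.m6a_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, ci_low = x$ci95[1], ci_high = x$ci95[2],
                 n_pos = x$n_pos, n_neg = x$n_neg, direction = x$direction)
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two markers measured on the same samples using the
#' DeLong structural-components covariance; two-sided normal p. Identical
#' markers (zero variance of the difference) are a flagged degenerate case
#' with difference 0 and p = 1.
#'
#' @param scores_a,scores_b Two markers on the same samples.
#' @param labels Positive-class indicator shared by both.
#' @param positive_direction `"higher"` or `"lower"`, applied to both.
#' @return One-row tibble: `auc_a`, `auc_b`, `diff`, `z`, `p_value`,
#'   `degenerate`.
#' @export
delong_compare <- function(scores_a, scores_b, labels,
                           positive_direction = c("higher", "lower")) {
  positive_direction <- match.arg(positive_direction)
  stopifnot(length(scores_a) == length(scores_b),
            length(scores_a) == length(labels))
  pos <- as.logical(labels)
  if (!any(pos) || all(pos)) abort("both classes must be present")
  if (positive_direction == "lower") {
    scores_a <- -scores_a; scores_b <- -scores_b
  }
  ca <- .delong_components(scores_a, pos)
  cb <- .delong_components(scores_b, pos)
  m <- sum(pos); n <- sum(!pos)
  s10 <- cov(cbind(ca$v10, cb$v10))
  s01 <- cov(cbind(ca$v01, cb$v01))
  S <- s10 / m + s01 / n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  d <- ca$auc - cb$auc
  degenerate <- var_diff <= 1e-12
  z <- if (degenerate) 0 else d / sqrt(var_diff)
  p <- if (degenerate) 1 else 2 * pnorm(-abs(z))
  tibble::tibble(auc_a = ca$auc, auc_b = cb$auc,
                 diff = if (degenerate) 0 else d, z = z, p_value = p,
                 degenerate = degenerate)
}
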