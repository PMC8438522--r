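# all permutations of 1..n as rows (n <= 8 kept tractable)
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Average ranks for ties; the p-value comes from exact enumeration of all
#' rank permutations for n <= 8 without ties, and from the t approximation
#' (`t = rho sqrt((n-2)/(1-rho^2))`) otherwise.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return One-row tibble: `rho`, `p_value`, `n`, `method`. Zero variance in
#'   either vector yields `rho = NA` with `method = "degenerate"`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) abort("need >= 3 observations")
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_, n = n,
                          method = "degenerate"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 8L && !ties) {
    perms <- .permutations(n)
    denom <- n * (n^2 - 1)
    rho_all <- 1 - 6 * rowSums(sweep(perms, 2L, rx)^2) / denom
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(tt), n - 2)
    }
    method <- "t-approx"
  }
  tibble::tibble(rho = rho, p_value = p, n = n, method = method)
}

#' Resampling co-expression screen for moderators of regulator-signature links
#'
#' The multiple co-expression procedure: (1) draw a subsample of `frac` of
#' the cohort without replacement; (2) within it, record the Spearman
#' correlation r1 between each marker regulator's expression and each
#' signature score (kept only when its p < 0.05, the relevance rule, unless
#' `filter_r1 = FALSE`) together with the median expression of every CEG;
#' (3) repeat `n_reps` times and, per (regulator, signature, CEG) triple,
#' correlate the CEG medians with the r1 values across replicates (Spearman
#' again, replicates with a filtered-out r1 dropped pairwise).
#'
#' @param expr Expression matrix (genes x samples).
#' @param signatures Signature-score tibble (`sample_id` + one column per
#'   signature), e.g. from [score_matrix()].
#' @param cegs CEG gene IDs (character) or a `ceg_set`.
#' @param regulators Marker regulators (default [coexp_regulators()]).
#' @param frac Subsample fraction (default 0.6).
#' @param n_reps Replicates (default 100).
#' @param filter_r1 Apply the p < 0.05 relevance rule to r1 (default `TRUE`).
#' @param min_valid Minimum contributing replicates for a triple's
#'   correlation to be reported (default 10).
#' @param seed Integer seed; the screen is fully reproducible from it.
#' @return Tibble: `regulator`, `signature`, `ceg`, `rho`, `p_value`,
#'   `n_valid`. Degenerate triples (constant medians, too few valid
#'   replicates) carry `rho = NA`.
#' @export
run_multicoexp <- function(expr, signatures, cegs,
                           regulators = coexp_regulators(), frac = 0.6,
                           n_reps = 100L, filter_r1 = TRUE, min_valid = 10L,
                           seed = 1L) {
  ceg_ids <- if (inherits(cegs, "ceg_set")) cegs$members else cegs
  common <- intersect(colnames(expr), signatures$sample_id)
  if (length(common) < 20L) abort("need >= 20 joined samples")
  expr <- expr[, common, drop = FALSE]
  sig <- signatures[match(common, signatures$sample_id), , drop = FALSE]
  regs <- intersect(regulators, rownames(expr))
  if (!length(regs)) abort("no marker regulator present in the matrix")
  if (length(regs) < length(regulators)) {
    warn(sprintf("%d regulator(s) missing from the matrix",
                 length(regulators) - length(regs)))
  }
  ceg_ids <- intersect(ceg_ids, rownames(expr))
  if (!length(ceg_ids)) abort("no CEG present in the matrix")
  sig_names <- setdiff(colnames(sig), "sample_id")
  keep_sig <- vapply(sig_names, function(s) mean(is.na(sig[[s]])) <= 0.5, TRUE)
  if (any(!keep_sig)) {
    warn(sprintf("skipping signature(s) missing for >50%% of samples: %s",
                 paste(sig_names[!keep_sig], collapse = ", ")))
  }
  sig_names <- sig_names[keep_sig]
  n <- length(common)
  m <- round(frac * n)
  set.seed(seed)

  r1 <- array(NA_real_, c(n_reps, length(regs), length(sig_names)),
              dimnames = list(NULL, regs, sig_names))
  med <- matrix(NA_real_, n_reps, length(ceg_ids),
                dimnames = list(NULL, ceg_ids))
  sig_mat <- as.matrix(sig[, sig_names, drop = FALSE])
  for (b in seq_len(n_reps)) {
    idx <- sample.int(n, m)
    sub_reg <- expr[regs, idx, drop = FALSE]
    sub_sig <- sig_mat[idx, , drop = FALSE]
    for (r in seq_along(regs)) {
      xr <- rank(sub_reg[r, ])
      for (s in seq_along(sig_names)) {
        ys <- sub_sig[, s]
        ok <- !is.na(ys)
        if (sum(ok) < 3L || sd(sub_reg[r, ok]) == 0 || sd(ys[ok]) == 0) next
        rho <- cor(rank(sub_reg[r, ok]), rank(ys[ok]))
        if (filter_r1) {
          p <- if (abs(rho) >= 1) 0 else {
            tt <- rho * sqrt((sum(ok) - 2) / (1 - rho^2))
            2 * pt(-abs(tt), sum(ok) - 2)
          }
          if (p >= 0.05) next
        }
        r1[b, r, s] <- rho
      }
    }
    med[b, ] <- apply(expr[ceg_ids, idx, drop = FALSE], 1L, median)
  }

  grid <- tidyr::expand_grid(regulator = regs, signature = sig_names,
                             ceg = ceg_ids)
  res <- pmap(grid, function(regulator, signature, ceg) {
    r1v <- r1[, regulator, signature]
    valid <- !is.na(r1v)
    nv <- sum(valid)
    if (nv < min_valid) {
      return(tibble::tibble(rho = NA_real_, p_value = NA_real_, n_valid = nv))
    }
    mv <- med[valid, ceg]
    if (sd(mv) == 0 || sd(r1v[valid]) == 0) {
      return(tibble::tibble(rho = NA_real_, p_value = NA_real_, n_valid = nv))
    }
    sc <- spearman_cor(mv, r1v[valid])
    tibble::tibble(rho = sc$rho, p_value = sc$p_value, n_valid = nv)
  }) |> list_rbind()
  bind_cols(grid, res)
}

#' Median-split contrast of a regulator / moderator pair on a signature
#'
#' Splits samples at the median of the regulator and of the moderator gene,
#' forming four groups, and compares the signature score across them
#' (pairwise Wilcoxon rank-sum tests, Holm-adjusted). Deterministic: no
#' resampling is involved.
#'
#' @param expr Expression matrix (genes x samples).
#' @param regulator,moderator Gene IDs, both present in `expr`.
#' @param signatures Signature-score tibble (`sample_id` + columns).
#' @param signature_name Column of `signatures` to contrast.
#' @return Tibble with one row per group (`regulator_level`,
#'   `moderator_level`, `n`, `mean_score`, `median_score`); pairwise test
#'   results attached as attribute `"tests"`.
#' @export
median_split_contrast <- function(expr, regulator, moderator, signatures,
                                  signature_name) {
  for (g in c(regulator, moderator)) {
    if (!g %in% rownames(expr)) abort(sprintf("gene '%s' not in the matrix", g))
  }
  common <- intersect(colnames(expr), signatures$sample_id)
  sig <- signatures[[signature_name]][match(common, signatures$sample_id)]
  if (is.null(sig)) abort(sprintf("no signature column '%s'", signature_name))
  rv <- expr[regulator, common]
  mv <- expr[moderator, common]
  hi_r <- rv > median(rv)
  hi_m <- mv > median(mv)
  for (v in list(hi_r, hi_m)) {
    if (max(mean(v), 1 - mean(v)) > 0.7) {
      warn("median ties place >70% of samples in one group")
    }
  }
  grp <- paste0(regulator, ifelse(hi_r, "_high", "_low"), ".",
                moderator, ifelse(hi_m, "_high", "_low"))
  df <- tibble::tibble(
    regulator_level = ifelse(hi_r, "high", "low"),
    moderator_level = ifelse(hi_m, "high", "low"),
    group = grp, score = sig)
  summary <- df |>
    group_by(.data$regulator_level, .data$moderator_level, .data$group) |>
    summarise(n = dplyr::n(), mean_score = mean(.data$score, na.rm = TRUE),
              median_score = median(.data$score, na.rm = TRUE),
              .groups = "drop")
  pairs <- combn(unique(grp), 2L)
  tests <- tibble::tibble(
    group_a = pairs[1L, ], group_b = pairs[2L, ],
    p_value = vapply(seq_len(ncol(pairs)), function(i) {
      suppressWarnings(wilcox.test(df$score[grp == pairs[1L, i]],
                                   df$score[grp == pairs[2L, i]])$p.value)
    }, 0))
  tests$p_adj <- p.adjust(tests$p_value, "holm")
  attr(summary, "tests") <- tests
  summary
}
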