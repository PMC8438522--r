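#' Kaplan-Meier curves
#'
#' @param km Tibble from [km_estimate()].
#' @return A ggplot object (step curves, one per group if present).
#' @export
plot_km <- function(km) {
  p <- ggplot2::ggplot(km, ggplot2::aes(x = .data$time, y = .data$survival))
  if ("group" %in% colnames(km)) {
    p <- p + ggplot2::geom_step(ggplot2::aes(colour = .data$group))
  } else {
    p <- p + ggplot2::geom_step()
  }
  p + ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "progression-free survival") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.m6a_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUC = %.3f (95%% CI %.3f-%.3f)",
                                  object$auc, object$ci95[1], object$ci95[2])) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.m6a_consensus <- function(object, ...) {
  ord <- order(object$labels$cluster)
  m <- object$consensus[ord, ord]
  df <- tibble::tibble(
    i = rep(seq_len(nrow(m)), times = ncol(m)),
    j = rep(seq_len(ncol(m)), each = nrow(m)),
    consensus = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$consensus)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "#08306b",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("consensus matrix (K = %d)", object$k)) +
    ggplot2::theme_minimal()
}

#' m6Ascore distribution by group or cluster
#'
#' @param scores Tibble from [compute_m6ascore()] / [dichotomize()].
#' @param by Column to group the violin plot by (default `"group"`).
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(scores, by = "group") {
  if (!by %in% colnames(scores)) abort(sprintf("no column '%s'", by))
  ggplot2::ggplot(scores, ggplot2::aes(x = factor(.data[[by]]),
                                       y = .data$score)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.5) +
    ggplot2::labs(x = by, y = "m6Ascore") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
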