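#' ROC curve points for a score table
#'
#' @param scores Named score vector or `lb_scores` tibble.
#' @param labels Positive gene ids (or logical vector).
#' @return A tibble with `threshold`, `tpr`, `fpr`, ordered for plotting.
#' @export
roc_points <- function(scores, labels) {
  s <- score_vector(scores)
  y <- label_vector(s, labels)
  ord <- order(-s)
  tibble(
    threshold = s[ord],
    tpr = cumsum(y[ord]) / sum(y),
    fpr = cumsum(!y[ord]) / sum(!y)
  )
}

#' Plot the ROC curve of a score table
#'
#' @inheritParams roc_points
#' @return A ggplot object.
#' @export
plot_roc <- function(scores, labels) {
  pts <- roc_points(scores, labels)
  pts <- dplyr::bind_rows(tibble(threshold = Inf, tpr = 0, fpr = 0), pts)
  a <- auroc(scores, labels)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC (AUROC = %.3f)", a)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a cross-validated gene score table
#'
#' Histogram of genome-wide log-odds with locus genes overlaid, the usual
#' first look at a prioritization run.
#'
#' @param object An `lb_scores` tibble from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lb_scores
#' @export
autoplot.lb_scores <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$log_odds,
                                       fill = .data$is_locus_gene)) +
    ggplot2::geom_histogram(bins = 50, position = "identity", alpha = 0.6) +
    ggplot2::labs(x = "Log-odds of disease association", y = "Genes",
                  fill = "Locus gene") +
    ggplot2::theme_minimal()
}

#' Plot a permutation-test null distribution
#'
#' @param object An `lb_permutation` from [topk_permutation_test()].
#' @param ... Unused.
#' @return A ggplot object with the observed statistic marked.
#' @method autoplot lb_permutation
#' @export
autoplot.lb_permutation <- function(object, ...) {
  df <- tibble(statistic = object$null)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$statistic)) +
    ggplot2::geom_bar() +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(
      x = "Likely positives in top window (null)", y = "Permutations",
      title = sprintf("Observed = %d, p = %.4g", object$observed,
                      object$empirical_p)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a fitted mixture threshold over the score histogram
#'
#' @param object An `lb_mixture` from [fit_threshold()].
#' @param scores The score vector the mixture was fitted to.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lb_mixture
#' @export
autoplot.lb_mixture <- function(object, scores, ...) {
  df <- tibble(score = scores)
  dens <- tibble(
    x = seq(min(scores), max(scores), length.out = 400)
  )
  for (j in seq_along(object$means)) {
    dens[[paste0("c", j)]] <- object$weights[j] *
      dnorm(dens$x, object$means[j], object$sds[j])
  }
  long <- tidyr::pivot_longer(dens, -"x", names_to = "component",
                              values_to = "density")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 60, fill = "grey85") +
    ggplot2::geom_line(data = long,
                       ggplot2::aes(x = .data$x, y = .data$density,
                                    colour = .data$component)) +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "Match score", y = "Density", colour = "Component") +
    ggplot2::theme_minimal()
}
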