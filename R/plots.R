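#' Plot an ROC curve with its bootstrap band
#'
#' @param object an `admira_roc` from [roc_with_bands()]
#' @param ... ignored
#' @return a ggplot
#' @export
autoplot.admira_roc <- function(object, ...) {
  ggplot2::ggplot() +
    ggplot2::geom_ribbon(
      data = object$band,
      ggplot2::aes(x = .data$fpr, ymin = .data$lo, ymax = .data$hi),
      fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_step(
      data = object$curve,
      ggplot2::aes(x = .data$fpr, y = .data$tpr),
      colour = "steelblue", linewidth = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  subtitle = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot ablation results across feature sets
#'
#' One panel per task, ensemble metric (mean over outer folds, error bars
#' +/- 1 sd) by feature-set combination.
#'
#' @param object an `admira_ablation` result
#' @param ... ignored
#' @return a ggplot
#' @export
autoplot.admira_ablation <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(feature_set = factor(.data$feature_set,
                                       levels = feature_set_combinations()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature_set,
                                   y = .data$ensemble_metric_mean)) +
    ggplot2::geom_col(fill = "steelblue", alpha = 0.8) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ensemble_metric_mean -
                     .data$ensemble_metric_sd,
                   ymax = .data$ensemble_metric_mean +
                     .data$ensemble_metric_sd),
      width = 0.25) +
    ggplot2::facet_wrap(~ task, scales = "free_y") +
    ggplot2::labs(x = "Feature set", y = "Ensemble metric (mean ± sd)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Lollipop plot of the top propagated feature importances
#'
#' @param importance tibble `feature`, `importance` (e.g. from
#'   [propagate_importance()] or an ensemble's `importance` element)
#' @param top number of features shown
#' @return a ggplot
#' @export
plot_importance <- function(importance, top = 20) {
  df <- utils::head(importance, top) |>
    dplyr::mutate(feature = stats::reorder(.data$feature,
                                           .data$importance))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$importance,
                                   y = .data$feature)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$importance,
                                       yend = .data$feature),
                          colour = "grey60") +
    ggplot2::geom_point(colour = "steelblue", size = 2) +
    ggplot2::labs(x = "Normalized importance", y = NULL) +
    ggplot2::theme_minimal()
}
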