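#' ROC curves of a cross-validation run
#'
#' One ROC curve per fold plus the pooled curve, from the retained
#' validation predictions.
#'
#' @param object A `pvae_cv` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pvae_cv <- function(object, ...) {
  per_fold <- object$predictions %>%
    dplyr::group_by(fold = .data$fold) %>%
    dplyr::group_modify(~ roc_points(.x$prob, .x$truth)) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(fold = factor(.data$fold))
  g <- glance(object)
  ggplot2::ggplot(per_fold, ggplot2::aes(.data$fpr, .data$tpr, colour = .data$fold)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = "Fold",
                  title = sprintf("Mean AUC %.3f ± %.3f", g$mean_auc, g$sd_auc)) +
    ggplot2::theme_minimal()
}

#' Training-loss history of a fitted model
#'
#' @param model A trained `pvae_model`.
#' @return A ggplot of the four loss terms per epoch.
#' @export
plot_loss_history <- function(model) {
  if (is.null(model$history)) abort("model has no training history")
  long <- tidyr::pivot_longer(model$history, -"epoch",
                              names_to = "term", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$loss, colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Horizontal bar chart of top attributed features
#'
#' @param object A `pvae_attribution` table.
#' @param annotations Optional annotation tibble for GTDB-style labels.
#' @param group `"responder"` or `"nonresponder"`.
#' @param k Number of features shown (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pvae_attribution <- function(object, annotations = NULL,
                                      group = c("responder", "nonresponder"),
                                      k = 20, ...) {
  group <- match.arg(group)
  top <- top_k_by_attribution(object, group, k)
  top$label <- if (!is.null(annotations)) {
    paste0(format_feature_label(top$feature_id, annotations), " [", top$feature_id, "]")
  } else top$feature_id
  top$label <- factor(top$label, levels = rev(top$label))
  ggplot2::ggplot(top, ggplot2::aes(.data$mean_ig, .data$label,
                                    fill = .data$mean_ig > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "Mean integrated-gradients score", y = NULL,
                  title = sprintf("Top %d features (%s)", nrow(top), group)) +
    ggplot2::theme_minimal()
}

#' Cumulative mutual-information contribution curve plot
#'
#' @param scores MI score tibble from [mi_scores()].
#' @return A ggplot of the cumulative contribution over feature rank.
#' @export
plot_cumulative_mi <- function(scores) {
  curve <- cumulative_mi_curve(scores)
  ggplot2::ggplot(curve, ggplot2::aes(.data$rank, .data$cumulative_fraction)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Feature rank (descending MI)",
                  y = "Cumulative MI fraction") +
    ggplot2::theme_minimal()
}
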