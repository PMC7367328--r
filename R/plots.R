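#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_ribbon geom_abline
#'   geom_col geom_point labs coord_fixed theme_minimal
#' @export
ggplot2::autoplot

#' Mean ROC curve with a standard-deviation band
#'
#' @param object A `stage_eval` from [train_eval()].
#' @param ... Unused.
#' @return A ggplot: vertically averaged ROC over the repeats (blue) with a
#'   pointwise +/- 1 sd band (grey), against the chance diagonal.
#' @method autoplot stage_eval
#' @export
autoplot.stage_eval <- function(object, ...) {
  df <- object$mean_roc
  g <- glance(object)
  ggplot(df, aes(x = .data$fpr, y = .data$tpr_mean)) +
    geom_ribbon(aes(ymin = pmax(.data$tpr_mean - .data$tpr_sd, 0),
                    ymax = pmin(.data$tpr_mean + .data$tpr_sd, 1)),
                fill = "grey70", alpha = 0.6) +
    geom_line(color = "steelblue", linewidth = 0.9) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", color = "grey40") +
    coord_fixed() +
    labs(x = "False positive rate", y = "True positive rate",
         title = sprintf("%s: mean ROC over %d repeats (AUC %.3f)",
                         object$model, g$repeats, g$mean_auc)) +
    theme_minimal()
}

#' Top-ranked feature importances
#'
#' @param object A `stage_ranking` from [rank_features()].
#' @param top_n Number of leading features to show.
#' @param ... Unused.
#' @return A ggplot bar chart of mean impurity-decrease importance.
#' @method autoplot stage_ranking
#' @export
autoplot.stage_ranking <- function(object, top_n = 20, ...) {
  df <- head(tidy(object), top_n)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot(df, aes(x = .data$importance, y = .data$feature)) +
    geom_col(fill = "steelblue") +
    labs(x = "Mean normalized impurity decrease", y = NULL,
         title = sprintf("Top %d of %d features", nrow(df), nrow(object))) +
    theme_minimal()
}

#' PCA projection scatter
#'
#' @param object A `stage_pca` from [pca_features()].
#' @param components Two component indices to plot.
#' @param ... Unused.
#' @return A ggplot of the projected coordinates, colored by stage label when
#'   available.
#' @method autoplot stage_pca
#' @export
autoplot.stage_pca <- function(object, components = c(1, 2), ...) {
  sc <- object$scores
  xs <- paste0("PC", components[1]); ys <- paste0("PC", components[2])
  ev <- object$eigenvalues / sum(object$eigenvalues)
  p <- if ("stage" %in% names(sc)) {
    ggplot(sc, aes(x = .data[[xs]], y = .data[[ys]], color = .data$stage))
  } else {
    ggplot(sc, aes(x = .data[[xs]], y = .data[[ys]]))
  }
  p + geom_point(alpha = 0.7) +
    labs(x = sprintf("%s (%.1f%%)", xs, 100 * ev[components[1]]),
         y = sprintf("%s (%.1f%%)", ys, 100 * ev[components[2]])) +
    theme_minimal()
}

#' Incremental feature-addition curve plot
#'
#' @param curve Tibble from [incremental_curve()].
#' @return A ggplot of mean accuracy versus number of top-ranked features.
#' @export
plot_incremental_curve <- function(curve) {
  ggplot(curve, aes(x = .data$k, y = .data$mean_accuracy,
                    color = .data$model)) +
    geom_line() + geom_point() +
    labs(x = "Top-ranked features included", y = "Mean accuracy",
         color = "Model") +
    theme_minimal()
}
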