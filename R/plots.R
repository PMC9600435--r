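# Figure builders mirroring the standard report layout: PR curves with a
# random-AP reference line, MCC heatmaps, CV box summaries and ranked
# importance plots. All return ggplot objects.

#' PR curves for one split
#'
#' One curve per model with AP in the legend and a horizontal line at the
#' random-classifier AP (the positive prevalence).
#'
#' @param report an [evaluate_stacked()] result.
#' @param split `"train"` or `"test"`.
#' @return a ggplot object.
#' @export
plot_pr_curves <- function(report, split = c("test", "train")) {
  split <- match.arg(split)
  curves <- report$pr_curves[[split]]
  ap <- report$ap[report$ap$split == split, ]
  df <- do.call(rbind, lapply(names(curves), function(nm) {
    cbind(curves[[nm]], model = nm)
  }))
  lab <- stats::setNames(
    sprintf("%s (AP = %.2f)", ap$model, ap$ap), ap$model)
  df$model <- factor(df$model, levels = ap$model, labels = lab[ap$model])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$recall, y = .data$precision,
                                   colour = .data$model)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_hline(yintercept = report$random_ap[[split]],
                        colour = "red", linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision", colour = NULL,
                  title = sprintf("Precision-recall (%s set)", split)) +
    ggplot2::theme_minimal()
}

#' MCC agreement heatmap for one split
#'
#' @param report an [evaluate_stacked()] result.
#' @param split `"train"` or `"test"`.
#' @return a ggplot object.
#' @export
plot_mcc_heatmap <- function(report, split = c("test", "train")) {
  split <- match.arg(split)
  m <- report$mcc[[split]]
  df <- expand.grid(a = rownames(m), b = colnames(m))
  df$mcc <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b,
                                   fill = .data$mcc)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$mcc)),
                       size = 2.5) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "MCC",
                  title = sprintf("Prediction agreement (%s set)", split)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Cross-validation AP summary boxes
#'
#' Per-model train and validation fold APs with the random-AP reference.
#'
#' @param cv a [cv_performance()] result.
#' @param random_ap optional reference prevalence to draw.
#' @return a ggplot object.
#' @export
plot_cv_ap <- function(cv, random_ap = NULL) {
  df <- rbind(
    data.frame(model = cv$folds$model, split = "train", ap = cv$folds$train_ap),
    data.frame(model = cv$folds$model, split = "validation",
               ap = cv$folds$validation_ap))
  g <- ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$ap,
                                        fill = .data$split)) +
    ggplot2::geom_boxplot(position = "dodge") +
    ggplot2::labs(x = NULL, y = "AP", fill = NULL,
                  title = "Cross-validated AP (train vs validation folds)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (!is.null(random_ap)) {
    g <- g + ggplot2::geom_hline(yintercept = random_ap, colour = "red",
                                 linetype = "dashed")
  }
  g
}

#' Ranked normalized meta-learner weights
#'
#' @param weights a [normalized_meta_weights()] result.
#' @return a ggplot object.
#' @export
plot_meta_weights <- function(weights) {
  weights$learner <- factor(weights$learner,
                            levels = rev(weights$learner))
  ggplot2::ggplot(weights,
                  ggplot2::aes(x = .data$normalized_weight,
                               y = .data$learner)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, colour = "red") +
    ggplot2::labs(x = "normalized meta-learner weight", y = NULL,
                  title = "Base-learner contributions") +
    ggplot2::theme_minimal()
}

#' Top permutation importances
#'
#' Horizontal bars of the top `top_n` features by median permutation
#' importance, with the zero reference line.
#'
#' @param imp a [permutation_importance()] result.
#' @param top_n how many features to show (default 10).
#' @return a ggplot object.
#' @export
plot_permutation_importance <- function(imp, top_n = 10L) {
  df <- utils::head(imp$importance, top_n)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$median_importance,
                                   y = .data$feature, fill = .data$view)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, colour = "red") +
    ggplot2::labs(x = sprintf("median importance (baseline %s - permuted)",
                              toupper(imp$metric)),
                  y = NULL, fill = "view",
                  title = sprintf("Top %d features by permutation importance",
                                  top_n)) +
    ggplot2::theme_minimal()
}
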