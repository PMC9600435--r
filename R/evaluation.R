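# Imbalance-aware evaluation: PR curves, Average Precision, Matthews
# correlation agreement matrices, cross-validated train/validation AP
# summaries and overfitting gaps.

#' Average Precision
#'
#' Step-wise, interpolation-free summarization of the precision-recall
#' curve: `AP = sum_n (R_n - R_{n-1}) * P_n` over descending unique score
#' thresholds; tied scores form a single threshold. Preferred over AUROC
#' for rare-positive problems because it does not reward correct ranking
#' of the abundant negatives.
#'
#' @param labels 0/1 labels with at least one positive.
#' @param scores finite numeric scores (higher = more positive).
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(labels, scores) {
  labels <- check_binary_labels(labels, require_both = FALSE)
  if (sum(labels) == 0) stop("no positive labels: AP undefined", call. = FALSE)
  stopifnot(length(labels) == length(scores), all(is.finite(scores)))
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  # indices closing each tie group = cumulative counts at unique thresholds
  last <- which(c(sc[-1] != sc[-length(sc)], TRUE))
  tp <- cumsum(lab)[last]
  n_at <- last
  precision <- tp / n_at
  recall <- tp / sum(labels)
  sum(diff(c(0, recall)) * precision)
}

#' Precision-recall curve points
#'
#' @param labels 0/1 labels with at least one positive.
#' @param scores finite numeric scores.
#' @return data frame with `threshold`, `recall` (non-decreasing),
#'   `precision`.
#' @export
pr_curve <- function(labels, scores) {
  labels <- check_binary_labels(labels, require_both = FALSE)
  if (sum(labels) == 0) stop("no positive labels", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  last <- which(c(sc[-1] != sc[-length(sc)], TRUE))
  tp <- cumsum(lab)[last]
  data.frame(threshold = sc[last],
             recall = tp / sum(labels),
             precision = tp / last)
}

#' Expected AP of an uninformative classifier
#'
#' A ranker carrying no class information has expected Average Precision
#' equal to the positive-class prevalence; this is the reference line
#' drawn under every PR summary.
#'
#' @param labels 0/1 labels, both classes present.
#' @return positive prevalence `n_positive / n`.
#' @export
random_ap <- function(labels) {
  labels <- check_binary_labels(labels)
  mean(labels)
}

#' Matthews correlation coefficient between two binary vectors
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` with `a`
#' as the reference; a zero denominator (one vector single-valued)
#' returns 0 by convention, which some one-class-only base learners do
#' hit.
#'
#' @param a,b 0/1 vectors of equal length.
#' @return value in `[-1, 1]`.
#' @export
mcc <- function(a, b) {
  a <- check_binary_labels(a, require_both = FALSE)
  b <- check_binary_labels(b, require_both = FALSE)
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  tp <- sum(a == 1 & b == 1); tn <- sum(a == 0 & b == 0)
  fp <- sum(a == 0 & b == 1); fn <- sum(a == 1 & b == 0)
  den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  if (den == 0) return(0)
  (as.numeric(tp) * tn - as.numeric(fp) * fn) / den
}

#' Pairwise MCC agreement matrix
#'
#' Symmetric matrix of Matthews correlations over every pair of model
#' prediction vectors plus the true labels — the heatmap view of
#' classifier diversity: low off-diagonal agreement among base learners
#' is what the meta-learner exploits.
#'
#' @param predicted_labels named list of 0/1 prediction vectors.
#' @param labels 0/1 true labels of the same length.
#' @return `(m+1) x (m+1)` symmetric matrix (models plus `"Labels"`).
#' @export
mcc_matrix <- function(predicted_labels, labels) {
  vecs <- c(predicted_labels, list(Labels = labels))
  nm <- names(vecs)
  m <- length(vecs)
  out <- matrix(0, m, m, dimnames = list(nm, nm))
  for (i in seq_len(m)) {
    for (j in i:m) {
      out[i, j] <- out[j, i] <- if (i == j) {
        if (length(unique(vecs[[i]])) > 1) 1 else 0
      } else mcc(vecs[[i]], vecs[[j]])
    }
  }
  out
}

#' Evaluate a fitted stacked model on a train/test split
#'
#' Computes, for every base learner, the SoftVote baseline and the
#' stacked model: AP and PR curves on the (refit) training set and on the
#' held-out test set, plus the two MCC agreement matrices (probabilities
#' thresholded at 0.5) and the random-AP reference of each split.
#'
#' @param model a [fit_stacked()] result.
#' @param train,test [multiview_dataset()]s.
#' @return object of class `evaluation_report` with `ap` (data frame:
#'   model, split, ap), `pr_curves`, `mcc`, `random_ap`.
#' @export
evaluate_stacked <- function(model, train, test) {
  one_split <- function(ds, split) {
    bp <- base_probabilities(model, ds)
    sv <- soft_vote(bp)
    scores <- c(lapply(seq_len(ncol(bp)), function(j) bp[, j]),
                list(sv$scores), list(predict(model, ds)))
    names(scores) <- c(colnames(bp), "SoftVote", "Stacked")
    ap <- vapply(scores, function(s) average_precision(ds$labels, s), numeric(1))
    curves <- lapply(scores, function(s) pr_curve(ds$labels, s))
    preds <- lapply(scores, function(s) as.integer(s > 0.5))
    list(ap = data.frame(model = names(scores), split = split,
                         ap = unname(ap), row.names = NULL),
         pr = curves,
         mcc = mcc_matrix(preds, ds$labels),
         random_ap = random_ap(ds$labels))
  }
  tr <- one_split(train, "train")
  te <- one_split(test, "test")
  structure(list(ap = rbind(tr$ap, te$ap),
                 pr_curves = list(train = tr$pr, test = te$pr),
                 mcc = list(train = tr$mcc, test = te$mcc),
                 random_ap = c(train = tr$random_ap, test = te$random_ap)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  wide <- stats::reshape(x$ap, idvar = "model", timevar = "split",
                         direction = "wide")
  names(wide) <- sub("^ap\\.", "", names(wide))
  cat("evaluation_report (AP per model per split):\n")
  print(wide, row.names = FALSE, digits = 3)
  cat(sprintf("random AP: train %.3f, test %.3f\n",
              x$random_ap["train"], x$random_ap["test"]))
  invisible(x)
}

#' Cross-validated train/validation AP per model
#'
#' Stratified k-fold on the training set. For every base learner and
#' fold: AP on the k-1 training folds (the model's own training data) and
#' on the held-out validation fold. The stacked model's fold scores come
#' from a full nested stacked fit inside the k-1 folds (inner out-of-fold
#' meta-features; the held-out fold is never touched during that fit).
#' SoftVote is evaluated from the per-fold base probabilities.
#'
#' @param train training [multiview_dataset()].
#' @param config a [stack_config()]; supplies specs, filter settings and
#'   the meta-learner.
#' @param k outer fold count.
#' @param seed integer seed.
#' @param include_stacked run the nested stacked fit per fold (the most
#'   expensive part).
#' @param inner_k fold count of the nested stacked fits.
#' @return object of class `cv_performance`: data frame `folds` (model,
#'   fold, train_ap, validation_ap) and data frame `medians`.
#' @export
cv_performance <- function(train, config = stack_config(), k = config$k,
                           seed = config$seed, include_stacked = TRUE,
                           inner_k = 3L) {
  specs <- config$specs %||% default_suite(names(train$views), seed)
  folds <- stratified_folds(train$labels, k, derive_seed(seed, 5L))
  rows <- list()
  for (f in seq_len(k)) {
    tr_idx <- which(folds != f)
    va_idx <- which(folds == f)
    fit_ds <- mv_subset(train, tr_idx)
    va_ds <- mv_subset(train, va_idx)
    fstate <- if ("microbial" %in% names(train$views)) {
      fit_view_filter(fit_ds$views$microbial, fit_ds$labels,
                      alpha = config$alpha, method = config$correction)
    } else NULL
    cw <- compute_class_weights(fit_ds$labels)
    tr_views <- prep_views(fit_ds, fstate)
    va_views <- prep_views(va_ds, fstate)
    bp_tr <- matrix(NA_real_, length(tr_idx), length(specs))
    bp_va <- matrix(NA_real_, length(va_idx), length(specs))
    for (j in seq_along(specs)) {
      sp <- specs[[j]]
      fb <- fit_base_learner(sp, spec_input(sp, tr_views), fit_ds$labels, cw)
      bp_tr[, j] <- predict_base(fb, spec_input(sp, tr_views))
      bp_va[, j] <- predict_base(fb, spec_input(sp, va_views))
      rows[[length(rows) + 1]] <- data.frame(
        model = sp$name, fold = f,
        train_ap = average_precision(fit_ds$labels, bp_tr[, j]),
        validation_ap = average_precision(va_ds$labels, bp_va[, j]))
    }
    rows[[length(rows) + 1]] <- data.frame(
      model = "SoftVote", fold = f,
      train_ap = average_precision(fit_ds$labels, soft_vote(bp_tr)$scores),
      validation_ap = average_precision(va_ds$labels, soft_vote(bp_va)$scores))
    if (include_stacked) {
      inner_cfg <- config
      inner_cfg$k <- as.integer(min(inner_k, min(table(fit_ds$labels))))
      inner_cfg$seed <- derive_seed(seed, 100L + f)
      inner_cfg$specs <- specs
      sm <- fit_stacked(fit_ds, inner_cfg)
      rows[[length(rows) + 1]] <- data.frame(
        model = "Stacked", fold = f,
        train_ap = average_precision(fit_ds$labels, predict(sm, fit_ds)),
        validation_ap = average_precision(va_ds$labels, predict(sm, va_ds)))
    }
  }
  df <- do.call(rbind, rows)
  meds <- do.call(rbind, lapply(split(df, df$model), function(d) {
    data.frame(model = d$model[1],
               median_train_ap = stats::median(d$train_ap),
               median_validation_ap = stats::median(d$validation_ap))
  }))
  rownames(meds) <- NULL
  structure(list(folds = df, medians = meds, k = k, seed = seed),
            class = "cv_performance")
}

#' Overfitting gap per model
#'
#' Median training-fold AP minus median validation-fold AP, grouped by
#' the view each model consumes (the stacked model and SoftVote span both
#' views).
#'
#' @param report a [cv_performance()] result.
#' @param specs optional list of [base_learner_spec()] used to annotate
#'   each model's view.
#' @return data frame with `model`, `view`, `gap`, in the report's model
#'   order.
#' @export
overfit_gap <- function(report, specs = NULL) {
  stopifnot(inherits(report, "cv_performance"))
  view_of <- c(Stacked = "both", SoftVote = "both")
  if (!is.null(specs)) {
    view_of <- c(stats::setNames(vapply(specs, `[[`, character(1), "view"),
                                 vapply(specs, `[[`, character(1), "name")),
                 view_of)
  }
  order_models <- unique(report$folds$model)
  meds <- report$medians[match(order_models, report$medians$model), ]
  data.frame(model = meds$model,
             view = unname(view_of[meds$model]),
             gap = meds$median_train_ap - meds$median_validation_ap,
             row.names = NULL)
}
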