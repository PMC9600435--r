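# The stacking core: out-of-fold probability meta-features from the
# per-view base-learner suite, an elastic-net logistic meta-learner fit on
# them by grid-searched cross-validation, base learners refit on the full
# training set for test-time prediction, and the SoftVote baseline.

#' Stacking configuration
#'
#' @param k fold count for the out-of-fold meta-feature construction and
#'   the meta-learner grid search (stratified).
#' @param seed master seed; fans out to folds, learners and the grid
#'   search.
#' @param alpha significance level of the ANOVA/FDR microbial filter.
#' @param correction multiple-test correction (`"BH"`, `"bonferroni"`,
#'   `"none"`).
#' @param meta_learner `"elasticnet"` (default), `"random-forest"` or
#'   `"softvote"`.
#' @param grid meta-learner hyperparameter grid, see [default_meta_grid()].
#' @param specs optional list of [base_learner_spec()]; defaults to
#'   [default_suite()] over the dataset's views.
#' @param scoring grid-search scoring metric (only `"ap"`, average
#'   precision, is implemented).
#' @return object of class `stack_config`.
#' @export
stack_config <- function(k = 5L, seed = 1L, alpha = 0.05, correction = "BH",
                         meta_learner = c("elasticnet", "random-forest", "softvote"),
                         grid = default_meta_grid(), specs = NULL,
                         scoring = "ap") {
  meta_learner <- match.arg(meta_learner)
  structure(list(k = as.integer(k), seed = as.integer(seed), alpha = alpha,
                 correction = correction, meta_learner = meta_learner,
                 grid = grid, specs = specs, scoring = scoring),
            class = "stack_config")
}

#' Default elastic-net meta-learner grid
#'
#' Exhaustive grid over penalty strength (7 log-spaced values, `10^-3` to
#' `10^3`) times l1-ratio `{0, 0.25, 0.5, 0.75, 1}`.
#'
#' @return list with elements `lambda` and `l1_ratio`.
#' @export
default_meta_grid <- function() {
  list(lambda = 10^seq(-3, 3), l1_ratio = c(0, 0.25, 0.5, 0.75, 1))
}

# Input for one spec given preprocessed views.
spec_input <- function(spec, prepped_views) {
  v <- prepped_views[[spec$view]]
  if (is.null(v)) stop(sprintf("view '%s' not present", spec$view), call. = FALSE)
  v
}

# Apply per-view preprocessing given a fitted microbial filter state:
# microbial -> filtered/transformed matrix, clinical -> passthrough.
prep_views <- function(ds, filter_state) {
  out <- ds$views
  if (!is.null(filter_state) && "microbial" %in% names(out)) {
    out$microbial <- apply_view_filter(filter_state, out$microbial)
  }
  out
}

#' Build out-of-fold probability meta-features
#'
#' Splits the training set into `k` stratified folds; in each round the
#' fold-complement is used to fit the (label-using) microbial filter and
#' every base learner, and only the held-out fold's predicted
#' positive-class probabilities are collected. Row `i` of the result was
#' therefore produced by models that never saw sample `i` — the property
#' that lets the meta-learner train on these columns without label
#' leakage. Per-fold models are discarded afterwards.
#'
#' @param train training [multiview_dataset()].
#' @param specs list of [base_learner_spec()].
#' @param k fold count (>= 2; every class needs >= k members).
#' @param seed integer seed (fold assignment is derived from it).
#' @param filter_alpha,filter_method microbial-filter settings refit
#'   inside each fold-complement.
#' @param class_weights optional [compute_class_weights()]; the default
#'   (`NULL`) recomputes them on each fold-complement, which keeps row
#'   `i` fully independent of sample `i`'s own label.
#' @param folds optional precomputed fold assignment (integer vector in
#'   `1:k`), overriding the seeded stratified assignment.
#' @return object of class `meta_features`: `values` (n x m matrix of
#'   out-of-fold probabilities), `fold_of_sample`, `column_names`.
#' @export
build_meta_features <- function(train, specs, k = 5L, seed = 1L,
                                filter_alpha = 0.05, filter_method = "BH",
                                class_weights = NULL, folds = NULL) {
  labels <- train$labels
  folds <- folds %||% stratified_folds(labels, k, derive_seed(seed, 2L))
  stopifnot(length(folds) == length(labels), all(folds %in% seq_len(k)))
  n <- length(labels)
  m <- length(specs)
  values <- matrix(NA_real_, n, m,
                   dimnames = list(train$sample_ids,
                                   vapply(specs, `[[`, character(1), "name")))
  for (f in seq_len(k)) {
    tr <- which(folds != f)
    va <- which(folds == f)
    fit_ds <- mv_subset(train, tr)
    fstate <- if ("microbial" %in% names(train$views)) {
      fit_view_filter(fit_ds$views$microbial, fit_ds$labels,
                      alpha = filter_alpha, method = filter_method)
    } else NULL
    cw <- class_weights %||% compute_class_weights(fit_ds$labels)
    tr_views <- prep_views(fit_ds, fstate)
    va_views <- prep_views(mv_subset(train, va), fstate)
    for (j in seq_len(m)) {
      sp <- specs[[j]]
      fb <- tryCatch(
        fit_base_learner(sp, spec_input(sp, tr_views), fit_ds$labels, cw),
        error = function(e) stop(sprintf(
          "base learner '%s' failed on fold %d: %s", sp$name, f,
          conditionMessage(e)), call. = FALSE))
      values[va, j] <- predict_base(fb, spec_input(sp, va_views))
    }
  }
  stopifnot(!anyNA(values), all(values >= 0 & values <= 1))
  structure(list(values = values, fold_of_sample = folds,
                 column_names = colnames(values)),
            class = "meta_features")
}

#' Fit the meta-learner on stacked meta-features
#'
#' Elastic-net logistic regression over the out-of-fold probability
#' columns, with exhaustive grid search over penalty strength and
#' l1-ratio scored by stratified cross-validated average precision; the
#' winning grid point is refit on all meta rows. Meta columns are already
#' on a common probability scale, so no internal standardization is
#' applied and the weights stay directly comparable.
#'
#' @param meta a [build_meta_features()] result (or a bare numeric matrix).
#' @param labels 0/1 labels aligned with the meta rows.
#' @param grid grid as in [default_meta_grid()] (non-empty).
#' @param k fold count of the grid-search CV.
#' @param seed integer seed for the CV folds.
#' @return object of class `meta_learner` with `coef`, `intercept`,
#'   `lambda`, `l1_ratio`, `cv_score` and the refit glmnet model.
#' @export
fit_meta_learner <- function(meta, labels, grid = default_meta_grid(),
                             k = 5L, seed = 1L) {
  X <- if (inherits(meta, "meta_features")) meta$values else as.matrix(meta)
  if (!all(is.finite(X))) stop("non-finite meta-features", call. = FALSE)
  labels <- check_binary_labels(labels)
  stopifnot(length(grid$lambda) >= 1, length(grid$l1_ratio) >= 1)
  # degenerate no-information case: every column constant; fall back to an
  # intercept-only model predicting the prevalence
  if (all(apply(X, 2, stats::var) == 0)) {
    nm <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
    return(structure(list(type = "elasticnet", model = NULL,
                          lambda = max(grid$lambda),
                          l1_ratio = grid$l1_ratio[1],
                          coef = stats::setNames(rep(0, ncol(X)), nm),
                          intercept = stats::qlogis(mean(labels)),
                          cv_score = mean(labels)),
                     class = "meta_learner"))
  }
  lambdas <- sort(unique(grid$lambda), decreasing = TRUE)
  # glmnet is happier fitting a path than a single lambda; fit a path
  # covering the grid and read predictions off at the grid points.
  path <- sort(unique(c(lambdas, 10^seq(-3, 1))), decreasing = TRUE)
  folds <- stratified_folds(labels, k, derive_seed(seed, 3L))
  score <- matrix(0, length(grid$l1_ratio), length(lambdas),
                  dimnames = list(NULL, NULL))
  for (f in seq_len(k)) {
    tr <- folds != f
    for (a in seq_along(grid$l1_ratio)) {
      fit <- glmnet::glmnet(pad_one(X[tr, , drop = FALSE]), labels[tr],
                            family = "binomial", alpha = grid$l1_ratio[a],
                            lambda = path, standardize = FALSE)
      pr <- stats::predict(fit, pad_one(X[!tr, , drop = FALSE]),
                           s = lambdas, type = "response")
      for (l in seq_along(lambdas)) {
        score[a, l] <- score[a, l] +
          average_precision(labels[!tr], pr[, l]) / k
      }
    }
  }
  # deterministic tie-break: smaller l1-ratio, then stronger penalty
  best <- which(score == max(score), arr.ind = TRUE)[1, ]
  best_alpha <- grid$l1_ratio[best[1]]
  best_lambda <- lambdas[best[2]]
  refit <- glmnet::glmnet(pad_one(X), labels, family = "binomial",
                          alpha = best_alpha, lambda = path,
                          standardize = FALSE)
  beta <- as.numeric(stats::coef(refit, s = best_lambda))
  names(beta) <- c("(Intercept)", colnames(pad_one(X)))
  beta <- beta[setdiff(names(beta), ".pad")]
  structure(list(type = "elasticnet", model = refit,
                 lambda = best_lambda, l1_ratio = best_alpha,
                 coef = beta[-1], intercept = unname(beta[1]),
                 cv_score = max(score)),
            class = "meta_learner")
}

# Predict positive-class probability from any meta-learner variant.
predict_meta <- function(meta_model, base_probs) {
  switch(meta_model$type,
    "elasticnet" = if (is.null(meta_model$model)) {
      as.numeric(stats::plogis(meta_model$intercept +
        as.matrix(base_probs) %*% meta_model$coef))
    } else as.numeric(stats::predict(
      meta_model$model, pad_one(base_probs), s = meta_model$lambda,
      type = "response")),
    "random-forest" = as.numeric(stats::predict(
      meta_model$model, data = as.data.frame(base_probs))$predictions[, "1"]),
    "softvote" = rowMeans(base_probs))
}

#' Fit the full multi-view stacked model
#'
#' Orchestrates the training pipeline on the training set only:
#' out-of-fold meta-feature construction (with the microbial filter refit
#' per fold), meta-learner fitting, then a refit of the microbial filter
#' and of every base learner on the full training set — the refits serve
#' test-time prediction, standard stacked-generalization practice.
#'
#' @param train training [multiview_dataset()].
#' @param config a [stack_config()].
#' @return object of class `stacked_model`.
#' @export
fit_stacked <- function(train, config = stack_config()) {
  stopifnot(inherits(config, "stack_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort_stage(name, conditionMessage(e)))
  }
  specs <- config$specs %||% default_suite(names(train$views), config$seed)
  cw <- stage("class_weights", compute_class_weights(train$labels))
  meta <- stage("build_meta_features",
    build_meta_features(train, specs, k = config$k, seed = config$seed,
                        filter_alpha = config$alpha,
                        filter_method = config$correction))
  meta_model <- stage("fit_meta_learner", switch(config$meta_learner,
    "elasticnet" = fit_meta_learner(meta, train$labels, grid = config$grid,
                                    k = config$k, seed = config$seed),
    "random-forest" = structure(list(
      type = "random-forest",
      model = ranger::ranger(
        x = as.data.frame(meta$values),
        y = factor(train$labels, levels = c("0", "1")),
        probability = TRUE, num.trees = 300L,
        seed = derive_seed(config$seed, 4L), num.threads = 1)),
      class = "meta_learner"),
    "softvote" = structure(list(type = "softvote"), class = "meta_learner")))
  fstate <- stage("fit_filter", if ("microbial" %in% names(train$views)) {
    fit_view_filter(train$views$microbial, train$labels,
                    alpha = config$alpha, method = config$correction)
  } else NULL)
  tr_views <- prep_views(train, fstate)
  fitted_bases <- stage("refit_bases", lapply(specs, function(sp) {
    fit_base_learner(sp, spec_input(sp, tr_views), train$labels, cw)
  }))
  names(fitted_bases) <- vapply(specs, `[[`, character(1), "name")
  structure(list(filter_state = fstate, specs = specs,
                 fitted_bases = fitted_bases, meta = meta_model,
                 meta_features = meta, k = config$k, seed = config$seed,
                 class_weights = cw, config = config),
            class = "stacked_model")
}

#' @export
print.stacked_model <- function(x, ...) {
  cat(sprintf("stacked_model: %d base learners, meta = %s (k = %d, seed = %d)\n",
              length(x$fitted_bases), x$meta$type, x$k, x$seed))
  if (x$meta$type == "elasticnet") {
    cat(sprintf("  chosen penalty: lambda = %g, l1-ratio = %g (CV AP %.3f)\n",
                x$meta$lambda, x$meta$l1_ratio, x$meta$cv_score))
  }
  if (!is.null(x$filter_state)) {
    cat(sprintf("  microbial filter: %d features kept of %d\n",
                length(x$filter_state$kept_features),
                length(x$filter_state$variance_mask)))
  }
  invisible(x)
}

#' Base-learner probability matrix for new samples
#'
#' Applies the stored filter state and collects every refit base
#' learner's positive-class probability.
#'
#' @param model a [fit_stacked()] result.
#' @param ds a [multiview_dataset()] with the fitted views/features.
#' @return n x m matrix of probabilities, columns named by learner.
#' @export
base_probabilities <- function(model, ds) {
  views <- prep_views(ds, model$filter_state)
  probs <- vapply(model$fitted_bases, function(fb) {
    predict_base(fb, spec_input(fb$spec, views))
  }, numeric(length(ds$sample_ids)))
  if (length(ds$sample_ids) == 1L) {
    probs <- matrix(probs, nrow = 1L,
                    dimnames = list(NULL, names(model$fitted_bases)))
  }
  rownames(probs) <- ds$sample_ids
  probs
}

#' Predict positive-class probabilities from a stacked model
#'
#' Full pipeline: stored microbial filter, refit base learners, fitted
#' meta-learner.
#'
#' @param object a [fit_stacked()] result.
#' @param ds a [multiview_dataset()].
#' @param ... unused.
#' @return numeric vector of probabilities in `[0, 1]`, one per sample.
#' @export
predict.stacked_model <- function(object, ds, ...) {
  p <- predict_meta(object$meta, base_probabilities(object, ds))
  pmin(pmax(as.numeric(p), 0), 1)
}

#' Soft-voting baseline
#'
#' Averages the base learners' positive-class probabilities; the label is
#' the class with the larger summed probability, ties going to the
#' negative class.
#'
#' @param base_probs n x m matrix of probabilities in `[0, 1]`.
#' @return list with `scores` (mean positive probability) and `labels`
#'   (0/1).
#' @export
soft_vote <- function(base_probs) {
  base_probs <- as.matrix(base_probs)
  if (nrow(base_probs) == 0 || ncol(base_probs) == 0) {
    stop("empty probability matrix", call. = FALSE)
  }
  stopifnot(all(base_probs >= 0 & base_probs <= 1))
  scores <- rowMeans(base_probs)
  list(scores = scores, labels = as.integer(scores > 0.5))
}
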