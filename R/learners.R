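# Heterogeneous base-learner suite behind one fit/predict surface.
# Every family exposes a positive-class probability (or a score mapped to
# [0,1]); families run with their ecosystem defaults — no per-base tuning.

BASE_FAMILIES <- c("sgd-logistic", "sgd-modified-huber", "k-nearest-neighbours",
                   "multilayer-perceptron", "quadratic-discriminant",
                   "random-forest", "histogram-gradient-boosting",
                   "dummy-prevalence")

#' Describe one base learner
#'
#' @param name identifier used in reports (e.g. `"HGBC_clin"`).
#' @param family model family id, one of `"sgd-logistic"`,
#'   `"sgd-modified-huber"`, `"k-nearest-neighbours"`,
#'   `"multilayer-perceptron"`, `"quadratic-discriminant"`,
#'   `"random-forest"`, `"histogram-gradient-boosting"`,
#'   `"dummy-prevalence"` (a constant-score control).
#' @param view name of the view the learner consumes.
#' @param supports_missing can the family ingest missing values?
#' @param supports_categorical can the family ingest factor columns?
#' @param use_class_weights apply data-space class weights when the family
#'   supports per-class or per-case weighting.
#' @param seed integer seed for stochastic families.
#' @param params named list of family-specific overrides.
#' @return object of class `base_learner_spec`.
#' @export
base_learner_spec <- function(name, family, view,
                              supports_missing = FALSE,
                              supports_categorical = FALSE,
                              use_class_weights = TRUE,
                              seed = 0L, params = list()) {
  family <- match.arg(family, BASE_FAMILIES)
  structure(list(name = name, family = family, view = view,
                 supports_missing = supports_missing,
                 supports_categorical = supports_categorical,
                 use_class_weights = use_class_weights,
                 seed = as.integer(seed), params = params),
            class = "base_learner_spec")
}

#' The default per-view base-learner suite
#'
#' Seven learners on the microbial view — SGD_LL (logistic-loss linear),
#' SGD_HL (modified-Huber-style large-margin linear), KNN, MLP, QDA, RF
#' and HGBC_otu — plus HGBC_clin on the clinical view when present.
#' Histogram gradient boosting is the only family applied to the clinical
#' view because it is the only one that natively handles missing values
#' and categorical features; the others would require imputation and
#' one-hot encoding. Class weighting is enabled on every family that
#' supports it.
#'
#' @param views character vector of available view names; must include
#'   `"microbial"`.
#' @param seed integer seed fanned out to each learner.
#' @return list of [base_learner_spec()] objects.
#' @export
default_suite <- function(views, seed = 1L) {
  known <- c("microbial", "clinical")
  if (length(setdiff(views, known))) {
    stop(sprintf("unknown view name '%s'", setdiff(views, known)[1]), call. = FALSE)
  }
  if (!"microbial" %in% views) {
    stop("the default suite requires the 'microbial' view", call. = FALSE)
  }
  mk <- function(name, family, view, miss = FALSE, cat = FALSE, cw = TRUE, off) {
    base_learner_spec(name, family, view, supports_missing = miss,
                      supports_categorical = cat, use_class_weights = cw,
                      seed = derive_seed(seed, off))
  }
  specs <- list(
    mk("SGD_LL", "sgd-logistic", "microbial", off = 11L),
    mk("SGD_HL", "sgd-modified-huber", "microbial", off = 12L),
    mk("KNN", "k-nearest-neighbours", "microbial", cw = FALSE, off = 13L),
    mk("MLP", "multilayer-perceptron", "microbial", off = 14L),
    mk("QDA", "quadratic-discriminant", "microbial", cw = FALSE, off = 15L),
    mk("RF", "random-forest", "microbial", off = 16L),
    mk("HGBC_otu", "histogram-gradient-boosting", "microbial",
       miss = TRUE, cat = TRUE, off = 17L))
  if ("clinical" %in% views) {
    specs <- c(specs, list(
      mk("HGBC_clin", "histogram-gradient-boosting", "clinical",
         miss = TRUE, cat = TRUE, off = 18L)))
  }
  specs
}

# ---- fitting ----------------------------------------------------------------

#' Fit one base learner
#'
#' @param spec a [base_learner_spec()].
#' @param X feature input: numeric matrix, or a data frame (factors/NAs
#'   allowed) for families with `supports_categorical`/`supports_missing`.
#' @param y 0/1 labels.
#' @param class_weights optional [compute_class_weights()] result; applied
#'   only when `spec$use_class_weights` and the family supports it.
#' @return object of class `fitted_base`.
#' @export
fit_base_learner <- function(spec, X, y, class_weights = NULL) {
  stopifnot(inherits(spec, "base_learner_spec"))
  y <- check_binary_labels(y)
  if (is.data.frame(X) && !spec$supports_categorical &&
      any(vapply(X, is.factor, logical(1)))) {
    stop(sprintf("learner '%s' cannot ingest categorical features", spec$name),
         call. = FALSE)
  }
  if (!spec$supports_missing && anyNA(X)) {
    stop(sprintf("learner '%s' cannot ingest missing values", spec$name),
         call. = FALSE)
  }
  cw <- if (isTRUE(spec$use_class_weights) && !is.null(class_weights)) {
    class_weights
  } else structure(c("0" = 1, "1" = 1), class = "class_weights")
  w <- case_weights(cw, y)
  fit <- switch(spec$family,
    "sgd-logistic" = fit_linear_logistic(spec, X, y, w),
    "sgd-modified-huber" = fit_linear_margin(spec, X, y, cw),
    "k-nearest-neighbours" = fit_knn(spec, X, y),
    "multilayer-perceptron" = fit_mlp(spec, X, y, w),
    "quadratic-discriminant" = fit_shrinkage_qda(spec, X, y),
    "random-forest" = fit_rf(spec, X, y, cw),
    "histogram-gradient-boosting" = fit_hgb(spec, X, y, w),
    "dummy-prevalence" = list(prevalence = mean(y)))
  structure(list(spec = spec, fit = fit), class = "fitted_base")
}

#' Positive-class probability from a fitted base learner
#'
#' @param object a [fit_base_learner()] result.
#' @param X new samples in the learner's input space.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict_base <- function(object, X) {
  stopifnot(inherits(object, "fitted_base"))
  spec <- object$spec
  fit <- object$fit
  p <- switch(spec$family,
    "sgd-logistic" = predict_linear_logistic(fit, X),
    "sgd-modified-huber" = predict_linear_margin(fit, X),
    "k-nearest-neighbours" = predict_knn(spec, fit, X),
    "multilayer-perceptron" = as.numeric(stats::predict(fit, pad_one(X))),
    "quadratic-discriminant" = predict_shrinkage_qda(fit, X),
    "random-forest" = {
      pr <- stats::predict(fit, data = as.data.frame(X))$predictions
      as.numeric(pr[, "1"])
    },
    "histogram-gradient-boosting" = predict_hgb(fit, X),
    "dummy-prevalence" = rep(fit$prevalence, nrow(X)))
  pmin(pmax(as.numeric(p), 0), 1)
}

# glmnet needs >= 2 columns; pad a zero column for 1-feature inputs.
pad_one <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) cbind(X, .pad = 0) else X
}

fit_linear_logistic <- function(spec, X, y, w) {
  lam <- spec$params$lambda %||% 1e-3
  # glmnet warns about classes under 8 observations; tiny folds are a
  # supported use here and the warning carries no action
  withCallingHandlers(
    glmnet::glmnet(pad_one(X), y, family = "binomial", alpha = 0,
                   lambda = c(10, 1, 0.1, 0.01, lam), weights = w,
                   standardize = FALSE),
    warning = function(wn) {
      if (grepl("fewer than 8", conditionMessage(wn))) {
        invokeRestart("muffleWarning")
      }
    })
}
predict_linear_logistic <- function(fit, X) {
  as.numeric(stats::predict(fit, pad_one(X), s = min(fit$lambda),
                            type = "response"))
}

# Linear large-margin scorer; decision values oriented on the training set
# and mapped to [0,1] by clip((d + 1) / 2).
fit_linear_margin <- function(spec, X, y, cw) {
  yf <- factor(y, levels = c("0", "1"))
  m <- e1071::svm(as.matrix(X), yf, kernel = "linear", scale = FALSE,
                  class.weights = unclass(cw))
  d <- attr(stats::predict(m, as.matrix(X), decision.values = TRUE),
            "decision.values")[, 1]
  flip <- mean(d[y == 1]) < mean(d[y == 0])
  list(model = m, flip = flip)
}
predict_linear_margin <- function(fit, X) {
  d <- attr(stats::predict(fit$model, as.matrix(X), decision.values = TRUE),
            "decision.values")[, 1]
  if (fit$flip) d <- -d
  pmin(pmax((d + 1) / 2, 0), 1)
}

# Lazy learner: store the training set; the neighbour-vote fraction is the
# probability-like score.
fit_knn <- function(spec, X, y) {
  list(X = as.matrix(X), y = factor(y, levels = c("0", "1")),
       k = spec$params$k %||% 5L)
}
predict_knn <- function(spec, fit, X) {
  with_seed(spec$seed, {
    pred <- class::knn(fit$X, as.matrix(X), fit$y, k = fit$k, prob = TRUE)
    pr <- attr(pred, "prob")
    ifelse(pred == "1", pr, 1 - pr)
  })
}

fit_mlp <- function(spec, X, y, w) {
  size <- spec$params$size %||% 8L
  with_seed(spec$seed,
    nnet::nnet(pad_one(X), y, size = size, entropy = TRUE,
               decay = spec$params$decay %||% 1e-3,
               maxit = spec$params$maxit %||% 200L,
               MaxNWts = 1e6, weights = w, trace = FALSE))
}

# Gaussian QDA with covariance shrinkage toward a scalar diagonal so the
# per-class covariance stays invertible when p approaches the class size
# (the operating regime of filtered OTU matrices).
fit_shrinkage_qda <- function(spec, X, y) {
  X <- as.matrix(X)
  reg <- spec$params$reg %||% 0.1
  cls <- lapply(c(0L, 1L), function(cl) {
    Xc <- X[y == cl, , drop = FALSE]
    mu <- colMeans(Xc)
    S <- stats::cov(Xc) * (nrow(Xc) - 1) / nrow(Xc)
    avg <- mean(diag(S))
    if (!is.finite(avg) || avg <= 0) avg <- 1
    S <- (1 - reg) * S + reg * avg * diag(ncol(X))
    ch <- chol(S + 1e-8 * diag(ncol(X)))
    list(mu = mu, chol = ch,
         logdet = 2 * sum(log(diag(ch))),
         logprior = log(nrow(Xc) / nrow(X)))
  })
  names(cls) <- c("0", "1")
  cls
}
predict_shrinkage_qda <- function(fit, X) {
  X <- as.matrix(X)
  logd <- vapply(fit, function(cl) {
    d <- sweep(X, 2, cl$mu)
    z <- backsolve(cl$chol, t(d), transpose = TRUE)
    -0.5 * colSums(z^2) - 0.5 * cl$logdet + cl$logprior
  }, numeric(nrow(X)))
  if (nrow(X) == 1L) logd <- matrix(logd, nrow = 1L)
  1 / (1 + exp(logd[, 1] - logd[, 2]))
}

fit_rf <- function(spec, X, y, cw) {
  yf <- factor(y, levels = c("0", "1"))
  ranger::ranger(x = as.data.frame(X), y = yf, probability = TRUE,
                 num.trees = spec$params$num_trees %||% 300L,
                 class.weights = unclass(cw)[levels(yf)],
                 seed = spec$seed, num.threads = 1)
}

# Histogram gradient boosting (xgboost "hist"): native NA handling;
# factor columns are integer-coded with stored levels, and unseen test
# levels map to the missing category (NA).
encode_hgb <- function(X, levels_map = NULL) {
  if (!is.data.frame(X)) {
    return(list(mat = as.matrix(X), levels = levels_map))
  }
  learn <- is.null(levels_map)
  if (learn) levels_map <- list()
  cols <- lapply(names(X), function(nm) {
    col <- X[[nm]]
    if (is.factor(col) || is.character(col)) {
      if (learn) {
        lv <- levels(factor(col))
        levels_map[[nm]] <<- lv
      } else lv <- levels_map[[nm]]
      as.numeric(match(as.character(col), lv))  # unseen level -> NA
    } else as.numeric(col)
  })
  mat <- do.call(cbind, cols)
  colnames(mat) <- names(X)
  list(mat = mat, levels = levels_map)
}
fit_hgb <- function(spec, X, y, w) {
  enc <- encode_hgb(X)
  dtrain <- xgboost::xgb.DMatrix(enc$mat, label = y, weight = w)
  params <- list(objective = "binary:logistic", tree_method = "hist",
                 eta = spec$params$eta %||% 0.1,
                 max_depth = spec$params$max_depth %||% 6L,
                 nthread = 1, seed = spec$seed)
  m <- xgboost::xgb.train(params = params, data = dtrain,
                          nrounds = spec$params$nrounds %||% 100L,
                          verbose = 0)
  list(model = m, levels = enc$levels, features = colnames(enc$mat))
}
predict_hgb <- function(fit, X) {
  enc <- encode_hgb(X, fit$levels)
  mat <- enc$mat[, fit$features, drop = FALSE]
  stats::predict(fit$model, xgboost::xgb.DMatrix(mat))
}
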