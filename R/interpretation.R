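# Two-level interpretability: which base learner matters (normalized
# meta-learner weights) and which original feature matters (permutation
# importance through the entire fitted pipeline, no retraining).

#' Ranked normalized meta-learner weights
#'
#' Raw regression weights of the linear meta-learner divided by the
#' maximum absolute weight, so the top base learner scores exactly +/-1;
#' signs are preserved (a negative weight means the meta-learner uses a
#' base learner's predictions by negating them).
#'
#' @param model a [fit_stacked()] result with an elastic-net meta-learner.
#' @return data frame (sorted by decreasing normalized weight) with
#'   `learner`, `raw_weight`, `normalized_weight`, `rank`.
#' @export
normalized_meta_weights <- function(model) {
  if (model$meta$type != "elasticnet") {
    stop(paste("meta-learner is not linear: weights unavailable;",
               "use permutation_importance() instead"), call. = FALSE)
  }
  raw <- model$meta$coef
  mx <- max(abs(raw))
  norm <- if (mx > 0) raw / mx else raw
  out <- data.frame(learner = names(raw), raw_weight = unname(raw),
                    normalized_weight = unname(norm))
  out <- out[order(-out$normalized_weight), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Permutation feature importance through the fitted pipeline
#'
#' For each original feature: shuffle that single column, push the
#' dataset through the full fitted pipeline (microbial filter, refit base
#' learners, meta-learner) without any refitting, and record
#' `baseline metric - permuted metric`. Repeated `n_repeats` times with
#' fresh permutations; the median over repeats is the headline value.
#' Features discarded by the microbial filter never reach a model, so
#' their importance is exactly zero for every repeat (kept rather than
#' omitted, so reports are comparable across filter settings). The
#' metric is average precision on the supplied (training) data.
#'
#' Per-column transforms are elementwise, so permuting a raw column and
#' transforming equals transforming and permuting; the implementation
#' permutes in the transformed space and recomputes only the learners on
#' the affected view, which is numerically identical to rerunning the
#' whole pipeline.
#'
#' @param model a [fit_stacked()] result.
#' @param ds the dataset to measure on (the training set in the standard
#'   report); both classes must be present.
#' @param n_repeats permutations per feature (>= 1).
#' @param seed integer seed; the report is bit-identical for a fixed seed
#'   and model.
#' @return object of class `importance_report`: `baseline`, `importance`
#'   (data frame: feature, view, median_importance), `repeats` (feature x
#'   repeat matrix), `n_repeats`, `metric`, `seed`.
#' @export
permutation_importance <- function(model, ds, n_repeats = 10L, seed = 1L) {
  stopifnot(inherits(model, "stacked_model"), n_repeats >= 1)
  labels <- check_binary_labels(ds$labels)
  views <- prep_views(ds, model$filter_state)
  base_p <- base_probabilities(model, ds)
  baseline <- average_precision(labels, predict_meta(model$meta, base_p))

  feats <- ds$feature_meta[, c("feature", "view")]
  kept_microbial <- model$filter_state$kept_features %||% character()
  learner_view <- vapply(model$fitted_bases, function(fb) fb$spec$view,
                         character(1))
  n <- length(labels)
  reps <- matrix(0, nrow(feats), n_repeats,
                 dimnames = list(feats$feature, NULL))
  with_seed(derive_seed(seed, 6L), {
    for (i in seq_len(nrow(feats))) {
      fname <- feats$feature[i]
      vname <- feats$view[i]
      active <- if (vname == "microbial") fname %in% kept_microbial else
        fname %in% colnames(views[[vname]])
      if (!active) next  # never reaches a model: importance exactly 0
      affected <- which(learner_view == vname)
      for (r in seq_len(n_repeats)) {
        perm_views <- views
        idx <- sample(n)
        if (is.data.frame(perm_views[[vname]])) {
          perm_views[[vname]][[fname]] <- perm_views[[vname]][[fname]][idx]
        } else {
          perm_views[[vname]][, fname] <- perm_views[[vname]][idx, fname]
        }
        bp <- base_p
        for (j in affected) {
          fb <- model$fitted_bases[[j]]
          bp[, j] <- predict_base(fb, spec_input(fb$spec, perm_views))
        }
        reps[i, r] <- baseline -
          average_precision(labels, predict_meta(model$meta, bp))
      }
    }
  })
  imp <- data.frame(feature = feats$feature, view = feats$view,
                    median_importance = apply(reps, 1, stats::median),
                    row.names = NULL)
  imp <- imp[order(-imp$median_importance), ]
  structure(list(baseline = baseline, importance = imp, repeats = reps,
                 n_repeats = as.integer(n_repeats), metric = "ap",
                 seed = as.integer(seed)),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat(sprintf("importance_report: baseline AP %.3f, %d repeats\n",
              x$baseline, x$n_repeats))
  cat("top features by median importance:\n")
  print(utils::head(x$importance, 10), row.names = FALSE, digits = 3)
  invisible(x)
}
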