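# Single-config end-to-end runner: split -> fit stacked + bases +
# SoftVote -> evaluate train/test -> CV summary -> interpretation ->
# serialized reports. One global seed fans out deterministically to every
# stage, so a rerun with the same config reproduces every numeric output.

#' Build a run configuration
#'
#' @param preset name of a synthetic cohort preset (see
#'   [cohort_presets()]); mutually exclusive with `data`.
#' @param data optional list with `clinical`, `microbial`, `label_column`,
#'   `positive_label` and optionally `id_column`, `categorical` — passed
#'   to [load_multiview()].
#' @param seed global seed.
#' @param test_fraction holdout fraction.
#' @param k fold count.
#' @param alpha ANOVA-filter significance level.
#' @param correction multiple-test correction method.
#' @param meta_learner `"elasticnet"`, `"random-forest"` or `"softvote"`.
#' @param n_repeats permutation-importance repeats.
#' @param exclude_features leakage guard: feature names dropped before
#'   any fitting (cohort-specific disease-related columns).
#' @param cv_stacked include the nested stacked fit in the CV summary.
#' @param figures also write PNG figures.
#' @return object of class `run_config`.
#' @export
run_config <- function(preset = "ibd-like-small", data = NULL, seed = 1L,
                       test_fraction = 0.2, k = 5L, alpha = 0.05,
                       correction = "BH", meta_learner = "elasticnet",
                       n_repeats = 10L, exclude_features = character(),
                       cv_stacked = TRUE, figures = FALSE) {
  structure(list(preset = preset, data = data, seed = as.integer(seed),
                 test_fraction = test_fraction, k = as.integer(k),
                 alpha = alpha, correction = correction,
                 meta_learner = meta_learner, n_repeats = as.integer(n_repeats),
                 exclude_features = exclude_features,
                 cv_stacked = isTRUE(cv_stacked), figures = isTRUE(figures)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y[intersect(names(y), names(formals(run_config)))])
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' Run the full experiment
#'
#' Loads or simulates the dataset, applies the leakage-guard feature
#' exclusions, splits into train/test, fits the stacked model, evaluates
#' every base learner, SoftVote and the stacked model on both splits,
#' runs the cross-validated AP summary and both interpretation reports,
#' and writes everything (JSON/CSV, optional PNG figures, a run log with
#' every seed and chosen hyperparameter) to `out_dir`. Any stage failure
#' aborts with a stage-tagged error.
#'
#' @param config a [run_config()] or path to a YAML file.
#' @param out_dir output directory (created).
#' @return invisibly, a list with the in-memory results (`model`,
#'   `split`, `evaluation`, `cv`, `weights`, `importance`).
#' @export
run_experiment <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  log_line <- function(...) {
    cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  }
  cat("", file = log_path)
  stage <- function(name, expr) {
    log_line("[stage] %s", name)
    tryCatch(expr, error = function(e) abort_stage(name, conditionMessage(e)))
  }

  ds <- stage("load_data", {
    if (!is.null(config$data)) {
      do.call(load_multiview, config$data)
    } else {
      preset <- cohort_presets(seed = derive_seed(config$seed, 10L))[[config$preset]]
      if (is.null(preset)) stop(sprintf("unknown preset '%s'", config$preset),
                                call. = FALSE)
      generate_multiview(preset)
    }
  })
  if (length(config$exclude_features)) {
    ds <- stage("exclude_features", mv_drop_features(ds, config$exclude_features))
    log_line("excluded features: %s",
             paste(config$exclude_features, collapse = ", "))
  }
  log_line("dataset: %d samples, %d positive", length(ds$sample_ids),
           sum(ds$labels))

  sp <- stage("split", split_train_test(ds, config$test_fraction,
                                        seed = config$seed))
  scfg <- stack_config(k = config$k, seed = config$seed, alpha = config$alpha,
                       correction = config$correction,
                       meta_learner = config$meta_learner)
  model <- stage("fit_stacked", fit_stacked(sp$train, scfg))
  if (model$meta$type == "elasticnet") {
    log_line("meta-learner grid choice: lambda = %g, l1_ratio = %g, CV AP = %.4f",
             model$meta$lambda, model$meta$l1_ratio, model$meta$cv_score)
  }
  log_line("seed fan-out: split %d, folds %d, grid-cv %d",
           derive_seed(config$seed, 1L), derive_seed(config$seed, 2L),
           derive_seed(config$seed, 3L))

  ev <- stage("evaluate", evaluate_stacked(model, sp$train, sp$test))
  cv <- stage("cv_performance",
              cv_performance(sp$train, scfg, include_stacked = config$cv_stacked))
  gaps <- overfit_gap(cv, model$specs)
  weights <- if (model$meta$type == "elasticnet") {
    stage("meta_weights", normalized_meta_weights(model))
  } else NULL
  imp <- stage("permutation_importance",
               permutation_importance(model, sp$train,
                                      n_repeats = config$n_repeats,
                                      seed = config$seed))

  stage("write_reports", {
    write_json_report(list(train_ids = sp$train$sample_ids,
                           test_ids = sp$test$sample_ids,
                           seed = config$seed,
                           test_fraction = config$test_fraction),
                      file.path(out_dir, "split.json"))
    data.table::fwrite(ev$ap, file.path(out_dir, "ap_table.csv"))
    write_json_report(list(ap = ev$ap, random_ap = as.list(ev$random_ap),
                           mcc_train = as.data.frame(ev$mcc$train),
                           mcc_test = as.data.frame(ev$mcc$test)),
                      file.path(out_dir, "evaluation.json"))
    data.table::fwrite(as.data.frame(ev$mcc$train, make.names = TRUE),
                       file.path(out_dir, "mcc_train.csv"), row.names = TRUE)
    data.table::fwrite(as.data.frame(ev$mcc$test, make.names = TRUE),
                       file.path(out_dir, "mcc_test.csv"), row.names = TRUE)
    data.table::fwrite(cv$folds, file.path(out_dir, "cv_folds.csv"))
    data.table::fwrite(merge(cv$medians, gaps, by = "model"),
                       file.path(out_dir, "cv_summary.csv"))
    if (!is.null(weights)) {
      data.table::fwrite(weights, file.path(out_dir, "meta_weights.csv"))
    }
    write_json_report(list(baseline_ap = imp$baseline,
                           n_repeats = imp$n_repeats, metric = imp$metric,
                           importance = imp$importance),
                      file.path(out_dir, "importance.json"))
    if (!is.null(model$filter_state)) {
      write_filter_state(model$filter_state,
                         file.path(out_dir, "filter_state.json"))
    }
    write_json_report(unclass(config), file.path(out_dir, "config.json"))
  })
  if (config$figures) {
    stage("figures", {
      ggplot2::ggsave(file.path(out_dir, "pr_test.png"),
                      plot_pr_curves(ev, "test"), width = 7, height = 5, dpi = 120)
      ggplot2::ggsave(file.path(out_dir, "pr_train.png"),
                      plot_pr_curves(ev, "train"), width = 7, height = 5, dpi = 120)
      ggplot2::ggsave(file.path(out_dir, "mcc_test.png"),
                      plot_mcc_heatmap(ev, "test"), width = 6, height = 5, dpi = 120)
      ggplot2::ggsave(file.path(out_dir, "cv_ap.png"),
                      plot_cv_ap(cv, random_ap(sp$train$labels)),
                      width = 7, height = 5, dpi = 120)
      if (!is.null(weights)) {
        ggplot2::ggsave(file.path(out_dir, "meta_weights.png"),
                        plot_meta_weights(weights), width = 6, height = 4,
                        dpi = 120)
      }
      ggplot2::ggsave(file.path(out_dir, "importance.png"),
                      plot_permutation_importance(imp), width = 7, height = 5,
                      dpi = 120)
    })
  }
  log_line("done")
  invisible(list(model = model, split = sp, evaluation = ev, cv = cv,
                 weights = weights, importance = imp, out_dir = out_dir))
}

#' Write a synthetic cohort to disk
#'
#' Simulates a preset cohort and writes the two view tables (and labels)
#' in the CSV dialect accepted by [load_multiview()].
#'
#' @param preset preset name, see [cohort_presets()].
#' @param seed integer seed.
#' @param out_dir output directory.
#' @return invisibly, the file paths.
#' @export
simulate_cohort <- function(preset = "ibd-like-small", seed = 1L, out_dir) {
  cfg <- cohort_presets(seed = seed)[[preset]]
  if (is.null(cfg)) stop(sprintf("unknown preset '%s'", preset), call. = FALSE)
  ds <- generate_multiview(cfg)
  write_multiview(ds, out_dir)
}
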