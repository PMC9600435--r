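# Multi-view dataset container, delimited-table IO and the train/test split.

#' Construct a multi-view dataset
#'
#' A `multiview_dataset` holds two (or more) sample-aligned feature views —
#' typically a small mixed-type `clinical` view and a large non-negative
#' numeric `microbial` (OTU abundance) view — plus a binary label vector.
#' All views share row order with `sample_ids`.
#'
#' @param views named list of feature tables. The microbial view must be a
#'   numeric matrix (finite, non-negative); mixed-type views are data frames
#'   whose categorical columns are factors.
#' @param labels binary label vector (0 = negative class, 1 = positive
#'   class), one per sample, both classes present.
#' @param sample_ids character vector of unique sample identifiers.
#' @param feature_meta optional data frame with columns `feature`, `view`,
#'   `kind` ("numeric"/"categorical") and `allow_missing`; built
#'   automatically when omitted.
#' @param allow_single_class permit a label vector with one class only
#'   (needed for prediction-time subsets; fitting functions still demand
#'   both classes).
#' @return an object of class `multiview_dataset`.
#' @export
multiview_dataset <- function(views, labels, sample_ids, feature_meta = NULL,
                              allow_single_class = FALSE) {
  if (is.null(names(views)) || any(!nzchar(names(views)))) {
    stop("views must be a named list", call. = FALSE)
  }
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids", call. = FALSE)
  n <- length(sample_ids)
  labels <- check_binary_labels(labels, require_both = !allow_single_class)
  if (length(labels) != n) stop("labels must have one entry per sample", call. = FALSE)
  for (vn in names(views)) {
    v <- views[[vn]]
    if (nrow(v) != n) {
      stop(sprintf("view '%s' has %d rows, expected %d", vn, nrow(v), n),
           call. = FALSE)
    }
    rownames(views[[vn]]) <- sample_ids
  }
  if (is.null(feature_meta)) {
    feature_meta <- do.call(rbind, lapply(names(views), function(vn) {
      v <- views[[vn]]
      kinds <- if (is.matrix(v)) rep("numeric", ncol(v)) else {
        vapply(v, function(col) if (is.factor(col) || is.character(col))
          "categorical" else "numeric", character(1))
      }
      miss <- if (is.matrix(v)) rep(FALSE, ncol(v)) else
        vapply(v, anyNA, logical(1))
      data.frame(feature = colnames(v), view = vn, kind = kinds,
                 allow_missing = miss, row.names = NULL)
    }))
  }
  if (anyDuplicated(feature_meta$feature)) {
    stop("every feature must belong to exactly one view", call. = FALSE)
  }
  ds <- structure(
    list(sample_ids = sample_ids, views = views, labels = labels,
         feature_meta = feature_meta),
    class = "multiview_dataset")
  validate_multiview(ds)
  ds
}

# Enforce the container invariants; called by the constructor and after IO.
validate_multiview <- function(ds) {
  n <- length(ds$sample_ids)
  for (vn in names(ds$views)) {
    v <- ds$views[[vn]]
    if (nrow(v) != n || !identical(rownames(v), ds$sample_ids)) {
      stop(sprintf("view '%s' is not aligned with sample_ids", vn), call. = FALSE)
    }
    meta <- ds$feature_meta[ds$feature_meta$view == vn, , drop = FALSE]
    if (is.matrix(v)) {
      if (!is.numeric(v)) stop(sprintf("view '%s' must be numeric", vn), call. = FALSE)
      bad <- !is.finite(v) & !is.na(v)
      if (any(bad)) stop(sprintf("view '%s' contains non-finite values", vn), call. = FALSE)
      if (any(v < 0, na.rm = TRUE) && vn == "microbial") {
        stop("microbial abundances must be non-negative", call. = FALSE)
      }
    }
    no_miss <- meta$feature[!meta$allow_missing]
    if (length(no_miss)) {
      vv <- if (is.matrix(v)) v[, intersect(colnames(v), no_miss), drop = FALSE] else
        v[, intersect(colnames(v), no_miss), drop = FALSE]
      if (anyNA(vv)) {
        stop(sprintf("missing values in view '%s' outside allow_missing columns", vn),
             call. = FALSE)
      }
    }
  }
  invisible(ds)
}

#' @export
print.multiview_dataset <- function(x, ...) {
  cat(sprintf("multiview_dataset: %d samples (%d positive)\n",
              length(x$sample_ids), sum(x$labels)))
  for (vn in names(x$views)) {
    cat(sprintf("  view '%s': %d features\n", vn, ncol(x$views[[vn]])))
  }
  invisible(x)
}

#' Subset a multi-view dataset by sample index
#'
#' @param ds a [multiview_dataset()].
#' @param idx integer or logical sample index.
#' @return a `multiview_dataset` restricted to the chosen samples.
#' @export
mv_subset <- function(ds, idx) {
  views <- lapply(ds$views, function(v) v[idx, , drop = FALSE])
  multiview_dataset(views, ds$labels[idx], ds$sample_ids[idx], ds$feature_meta,
                    allow_single_class = TRUE)
}

#' Drop named features from a dataset
#'
#' Used as the leakage guard: cohort-specific disease-related columns
#' (disease subtype, extent, history and the like) are removed before any
#' fitting so the model cannot learn label shortcuts.
#'
#' @param ds a [multiview_dataset()].
#' @param features character vector of feature names to drop.
#' @return the dataset without those features.
#' @export
mv_drop_features <- function(ds, features) {
  if (!length(features)) return(ds)
  views <- lapply(ds$views, function(v) {
    keep <- setdiff(colnames(v), features)
    v[, keep, drop = FALSE]
  })
  meta <- ds$feature_meta[!ds$feature_meta$feature %in% features, , drop = FALSE]
  multiview_dataset(views, ds$labels, ds$sample_ids, meta)
}

#' Load a multi-view dataset from two delimited tables
#'
#' Reads a clinical table and a microbial abundance table (CSV or TSV,
#' header row, shared sample-identifier column), joins them by identifier
#' (inner join; samples present in only one table are dropped with a
#' message, fully disjoint id sets are an error) and maps the label column
#' to 0/1. Empty fields and the literal "NA" are both read as missing; no
#' imputation is ever applied. Categorical columns are declared, never
#' inferred from content.
#'
#' @param clinical_table,microbial_table paths to the two delimited tables.
#' @param label_column name of the label column (present in exactly one
#'   table).
#' @param positive_label the label value mapped to 1; every other single
#'   value maps to 0.
#' @param id_column name of the sample-identifier column (default
#'   `"sample_id"`).
#' @param categorical character vector naming the clinical columns to treat
#'   as categorical (sidecar schema).
#' @param allow_missing character vector naming columns where missing
#'   values are permitted; defaults to all clinical feature columns.
#' @return a [multiview_dataset()].
#' @export
load_multiview <- function(clinical_table, microbial_table, label_column,
                           positive_label, id_column = "sample_id",
                           categorical = character(), allow_missing = NULL) {
  read_tab <- function(path) {
    as.data.frame(data.table::fread(path, na.strings = c("", "NA"),
                                    colClasses = list(character = id_column)))
  }
  clin <- read_tab(clinical_table)
  micr <- read_tab(microbial_table)
  for (tb in list(clin, micr)) {
    if (!id_column %in% names(tb)) {
      stop(sprintf("id column '%s' missing from an input table", id_column),
           call. = FALSE)
    }
  }
  if (anyDuplicated(clin[[id_column]]) || anyDuplicated(micr[[id_column]])) {
    stop("duplicate sample ids in input tables", call. = FALSE)
  }
  in_clin <- label_column %in% names(clin)
  in_micr <- label_column %in% names(micr)
  if (in_clin == in_micr) {
    stop("label column must be present in exactly one table", call. = FALSE)
  }
  ids <- intersect(clin[[id_column]], micr[[id_column]])
  if (!length(ids)) stop("no overlapping samples between the two tables", call. = FALSE)
  n_drop <- (nrow(clin) - length(ids)) + (nrow(micr) - length(ids))
  if (n_drop > 0) message(sprintf("dropping %d samples present in only one table", n_drop))
  clin <- clin[match(ids, clin[[id_column]]), , drop = FALSE]
  micr <- micr[match(ids, micr[[id_column]]), , drop = FALSE]

  lab_raw <- if (in_clin) clin[[label_column]] else micr[[label_column]]
  if (anyNA(lab_raw)) stop("missing label for at least one sample", call. = FALSE)
  lv <- unique(lab_raw)
  if (length(lv) > 2) stop("label column has more than 2 distinct values", call. = FALSE)
  if (!positive_label %in% lv) {
    stop(sprintf("positive label '%s' not found in label column", positive_label),
         call. = FALSE)
  }
  labels <- as.integer(lab_raw == positive_label)

  clin_feats <- setdiff(names(clin), c(id_column, label_column))
  micr_feats <- setdiff(names(micr), c(id_column, label_column))
  clin_df <- clin[, clin_feats, drop = FALSE]
  for (cc in intersect(categorical, clin_feats)) clin_df[[cc]] <- factor(clin_df[[cc]])
  micr_mat <- as.matrix(micr[, micr_feats, drop = FALSE])
  storage.mode(micr_mat) <- "double"
  if (anyNA(micr_mat)) stop("microbial view contains missing values", call. = FALSE)

  if (is.null(allow_missing)) allow_missing <- clin_feats
  meta <- rbind(
    data.frame(feature = clin_feats, view = "clinical",
               kind = ifelse(clin_feats %in% categorical, "categorical", "numeric"),
               allow_missing = clin_feats %in% allow_missing),
    data.frame(feature = micr_feats, view = "microbial", kind = "numeric",
               allow_missing = FALSE))
  multiview_dataset(list(clinical = clin_df, microbial = micr_mat),
                    labels, ids, meta)
}

#' Write a multi-view dataset to delimited tables
#'
#' Writes `clinical.csv` (sample id + clinical features + label) and
#' `microbial.csv` (sample id + abundances) in the dialect accepted by
#' [load_multiview()]; missing values are written as empty fields so a
#' round trip reproduces the missingness pattern exactly.
#'
#' @param ds a [multiview_dataset()].
#' @param dir output directory (created if needed).
#' @param label_column name for the label column (default `"label"`).
#' @param id_column name for the identifier column.
#' @return invisibly, the two file paths.
#' @export
write_multiview <- function(ds, dir, label_column = "label",
                            id_column = "sample_id") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # format doubles at full precision so a write/load round trip is exact
  fmt <- function(df) {
    for (j in seq_along(df)) {
      if (is.double(df[[j]])) {
        df[[j]] <- ifelse(is.na(df[[j]]), NA_character_,
                          sprintf("%.17g", df[[j]]))
      }
    }
    df
  }
  clin <- fmt(cbind(stats::setNames(data.frame(ds$sample_ids), id_column),
                    as.data.frame(ds$views$clinical),
                    stats::setNames(data.frame(ds$labels), label_column)))
  micr <- fmt(cbind(stats::setNames(data.frame(ds$sample_ids), id_column),
                    as.data.frame(ds$views$microbial)))
  paths <- file.path(dir, c("clinical.csv", "microbial.csv"))
  data.table::fwrite(clin, paths[1], na = "")
  data.table::fwrite(micr, paths[2], na = "")
  invisible(paths)
}

#' Split a dataset into training and test sets
#'
#' Random 80/20-style holdout split. Stratification (on by default)
#' preserves the class imbalance that the precision-recall evaluation
#' assumes: per-class test counts are the rounded per-class proportions.
#'
#' @param ds a [multiview_dataset()].
#' @param test_fraction proportion of samples held out, in (0, 1).
#' @param seed integer seed; the split is deterministic given the seed.
#' @param stratify draw the test set per class (default `TRUE`).
#' @return an object of class `split_result` with elements `train`,
#'   `test`, `seed`, `test_fraction`.
#' @export
split_train_test <- function(ds, test_fraction = 0.2, seed = 1, stratify = TRUE) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  n <- length(ds$sample_ids)
  if (n < 5) stop("need at least 5 samples to split", call. = FALSE)
  test_idx <- with_seed(derive_seed(seed, 1L), {
    if (stratify) {
      if (any(table(ds$labels) < 2)) {
        stop("each class needs >= 2 samples for a stratified split", call. = FALSE)
      }
      unlist(lapply(c(0L, 1L), function(cls) {
        idx <- which(ds$labels == cls)
        n_test <- round(length(idx) * test_fraction)
        n_test <- max(0L, min(length(idx) - 1L, n_test))
        sample(idx, n_test)
      }))
    } else {
      sample(n, round(n * test_fraction))
    }
  })
  test_idx <- sort(test_idx)
  structure(list(train = mv_subset(ds, setdiff(seq_len(n), test_idx)),
                 test = mv_subset(ds, test_idx),
                 seed = seed, test_fraction = test_fraction),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("split_result: %d train / %d test (test fraction %.2f, seed %d)\n",
              length(x$train$sample_ids), length(x$test$sample_ids),
              x$test_fraction, x$seed))
  invisible(x)
}
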