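# Independent oracles and small fixture builders shared across tests.
# These deliberately use naive loop-based formulations so they stay
# independent of the package's vectorized implementations.

# Brute-force average precision: enumerate every unique score as a
# threshold, compute precision/recall from raw counts, and accumulate the
# step sum. O(n^2).
ap_bruteforce <- function(labels, scores) {
  thr <- sort(unique(scores), decreasing = TRUE)
  ap <- 0
  recall_prev <- 0
  n_pos <- sum(labels == 1)
  for (t in thr) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    precision <- tp / sum(sel)
    recall <- tp / n_pos
    ap <- ap + (recall - recall_prev) * precision
    recall_prev <- recall
  }
  ap
}

# Direct-formula MCC from a confusion table.
mcc_from_counts <- function(tp, tn, fp, fn) {
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

sample_skewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  mean((x - m)^3) / s^3
}

# Small two-view dataset with a planted clinical and microbial signal.
tiny_mv <- function(n = 40, p_micro = 20, seed = 1, signal = 2,
                    pos_frac = 0.3) {
  generate_multiview(synthetic_config(
    n_samples = n, positive_fraction = pos_frac, n_microbial = p_micro,
    n_informative_microbial = max(2L, p_micro %/% 5L),
    microbial_effect = signal, clinical_effect = signal,
    n_clinical_numeric = 3, n_clinical_categorical = 1,
    n_informative_clinical = 1, missing_rate_clinical = 0.05,
    sparsity = 0.3, seed = seed))
}

# Microbial-only dataset (drops the clinical view).
micro_only <- function(ds) {
  multiview_dataset(ds$views["microbial"], ds$labels, ds$sample_ids,
                    ds$feature_meta[ds$feature_meta$view == "microbial", ])
}

# Moderate-signal configuration with complementary (disjoint) informative
# sets in the two views: each single view reaches mid-range AP, the
# regime where combining views is expected to help.
complementary_config <- function(seed) {
  synthetic_config(n_samples = 160, positive_fraction = 0.25,
                   n_microbial = 300, n_informative_microbial = 20,
                   microbial_effect = 1.0, clinical_effect = 1.5,
                   n_clinical_numeric = 4, n_clinical_categorical = 3,
                   n_informative_clinical = 2, sparsity = 0.3,
                   missing_rate_clinical = 0.05, seed = seed)
}

# Fast spec list for structural stacking tests.
fast_specs <- function(seed = 1) {
  list(
    base_learner_spec("SGD_LL", "sgd-logistic", "microbial", seed = seed),
    base_learner_spec("RF", "random-forest", "microbial",
                      seed = seed, params = list(num_trees = 100L)),
    base_learner_spec("DUMMY", "dummy-prevalence", "microbial", seed = seed))
}

# 20-replicate complementary-views study: test-set AP of the stacked model
# and of every base learner, plus the normalized meta weights. Memoised so
# several test files can share one computation.
dominance_study <- local({
  env <- new.env()
  function(n_seeds = 20) {
    key <- paste0("s", n_seeds)
    if (is.null(env[[key]])) {
      res <- lapply(seq_len(n_seeds), function(s) {
        ds <- generate_multiview(complementary_config(seed = s))
        sp <- split_train_test(ds, 0.25, seed = s)
        m <- fit_stacked(sp$train, stack_config(k = 5, seed = s))
        bp <- base_probabilities(m, sp$test)
        aps <- apply(bp, 2, function(x) average_precision(sp$test$labels, x))
        list(ap = c(Stacked = average_precision(sp$test$labels,
                                                predict(m, sp$test)), aps),
             weights = normalized_meta_weights(m))
      })
      env[[key]] <- list(
        ap = do.call(rbind, lapply(res, `[[`, "ap")),
        weights = lapply(res, `[[`, "weights"))
    }
    env[[key]]
  }
})
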