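test_that("meta-feature matrix has the right shape, range and fold bookkeeping", {
  ds <- micro_only(tiny_mv(n = 40, p_micro = 20, seed = 6, pos_frac = 0.3))
  specs <- fast_specs(seed = 2)
  mf <- build_meta_features(ds, specs, k = 4, seed = 2)
  expect_equal(dim(mf$values), c(40, 3))
  expect_equal(mf$column_names, c("SGD_LL", "RF", "DUMMY"))
  expect_true(all(mf$values >= 0 & mf$values <= 1))
  expect_setequal(unique(mf$fold_of_sample), 1:4)
  # stratified: every fold contains both classes
  for (f in 1:4) {
    expect_length(unique(ds$labels[mf$fold_of_sample == f]), 2)
  }
})

test_that("a prevalence-predicting spec yields fold-complement prevalences", {
  ds <- micro_only(tiny_mv(n = 30, p_micro = 10, seed = 3, pos_frac = 0.4))
  specs <- list(base_learner_spec("DUMMY", "dummy-prevalence", "microbial"))
  mf <- build_meta_features(ds, specs, k = 3, seed = 5)
  for (f in 1:3) {
    expected <- mean(ds$labels[mf$fold_of_sample != f])
    got <- mf$values[mf$fold_of_sample == f, 1]
    expect_equal(unname(got), rep(expected, length(got)))
  }
})

test_that("meta-feature construction is deterministic for a fixed seed", {
  ds <- micro_only(tiny_mv(n = 30, p_micro = 15, seed = 4))
  specs <- fast_specs(seed = 9)
  m1 <- build_meta_features(ds, specs, k = 3, seed = 11)
  m2 <- build_meta_features(ds, specs, k = 3, seed = 11)
  expect_identical(m1$values, m2$values)
  m3 <- build_meta_features(ds, specs, k = 3, seed = 12)
  expect_false(identical(m1$values, m3$values))
})

test_that("meta-feature row i is invariant to sample i's own label", {
  ds <- micro_only(tiny_mv(n = 24, p_micro = 12, seed = 10, pos_frac = 0.5))
  specs <- list(
    base_learner_spec("SGD_LL", "sgd-logistic", "microbial", seed = 1),
    base_learner_spec("RF", "random-forest", "microbial", seed = 1,
                      params = list(num_trees = 100L)))
  folds <- stratified_folds(ds$labels, 3, seed = 99)
  base <- build_meta_features(ds, specs, k = 3, seed = 1, folds = folds)
  for (i in c(2L, 13L)) {
    mut <- ds
    mut$labels[i] <- 1L - mut$labels[i]
    mutated <- build_meta_features(mut, specs, k = 3, seed = 1, folds = folds)
    expect_identical(base$values[i, ], mutated$values[i, ],
                     info = sprintf("sample %d", i))
  }
})

test_that("two-fold construction matches a hand-rolled implementation", {
  ds <- micro_only(tiny_mv(n = 10, p_micro = 6, seed = 15, pos_frac = 0.4))
  spec <- base_learner_spec("SGD_LL", "sgd-logistic", "microbial", seed = 3)
  folds <- stratified_folds(ds$labels, 2, seed = 31)
  mf <- build_meta_features(ds, list(spec), k = 2, seed = 31, folds = folds)
  manual <- numeric(10)
  for (f in 1:2) {
    tr <- which(folds != f); va <- which(folds == f)
    fs <- fit_view_filter(ds$views$microbial[tr, , drop = FALSE], ds$labels[tr])
    cw <- compute_class_weights(ds$labels[tr])
    fb <- fit_base_learner(
      spec, apply_view_filter(fs, ds$views$microbial[tr, , drop = FALSE]),
      ds$labels[tr], cw)
    manual[va] <- predict_base(
      fb, apply_view_filter(fs, ds$views$microbial[va, , drop = FALSE]))
  }
  expect_equal(unname(mf$values[, 1]), manual, tolerance = 1e-12)
})

test_that("grid search selects a perfect predictor column and weights it most", {
  set.seed(20)
  n <- 40
  labels <- rep(c(0L, 1L), each = 20)
  meta <- cbind(perfect = labels,
                noise1 = runif(n), noise2 = runif(n))
  ml <- fit_meta_learner(meta, labels, k = 4, seed = 2)
  # held-out AP of the selected model is 1: refit predictions rank perfectly
  pred <- mvstack:::predict_meta(ml, meta)
  expect_equal(average_precision(labels, pred), 1)
  expect_equal(names(which.max(abs(ml$coef))), "perfect")
})

test_that("constant meta-features give prevalence-level predictions", {
  labels <- rep(c(0L, 1L, 0L, 0L), 10)
  meta <- matrix(0.5, 40, 3, dimnames = list(NULL, c("a", "b", "c")))
  ml <- fit_meta_learner(meta, labels, k = 4, seed = 3)
  pred <- mvstack:::predict_meta(ml, meta)
  expect_true(all(abs(pred - mean(labels)) < 1e-6))
})

test_that("a single-point grid is selected as-is", {
  set.seed(8)
  labels <- rep(c(0L, 1L), 15)
  meta <- cbind(a = runif(30), b = runif(30))
  ml <- fit_meta_learner(meta, labels,
                         grid = list(lambda = 0.1, l1_ratio = 0.5),
                         k = 3, seed = 1)
  expect_equal(ml$lambda, 0.1)
  expect_equal(ml$l1_ratio, 0.5)
})

test_that("an enormous penalty zeroes the weights and balanced data predicts 0.5", {
  set.seed(12)
  labels <- rep(c(0L, 1L), 20)
  meta <- cbind(a = runif(40), b = runif(40))
  ml <- fit_meta_learner(meta, labels,
                         grid = list(lambda = 1e6, l1_ratio = 0),
                         k = 4, seed = 1)
  expect_true(all(abs(ml$coef) < 1e-6))
  expect_true(all(abs(mvstack:::predict_meta(ml, meta) - 0.5) < 1e-3))
})

test_that("fit_stacked assembles the full pipeline over both views", {
  ds <- tiny_mv(n = 60, p_micro = 40, seed = 30, pos_frac = 0.3)
  m <- fit_stacked(ds, stack_config(k = 3, seed = 7))
  expect_s3_class(m, "stacked_model")
  expect_length(m$fitted_bases, 8)
  expect_length(m$meta$coef, 8)
  expect_equal(names(m$meta$coef), names(m$fitted_bases))
  p <- predict(m, ds)
  expect_length(p, 60)
  expect_true(all(p >= 0 & p <= 1))
  # single-sample prediction
  expect_length(predict(m, mv_subset(ds, 5)), 1)
})

test_that("microbial-only data uses the seven-learner path", {
  ds <- micro_only(tiny_mv(n = 50, p_micro = 30, seed = 31, pos_frac = 0.3))
  m <- fit_stacked(ds, stack_config(k = 3, seed = 2))
  expect_length(m$fitted_bases, 7)
  expect_false("HGBC_clin" %in% names(m$fitted_bases))
})

test_that("the meta-learner is configurable", {
  ds <- tiny_mv(n = 50, p_micro = 25, seed = 32, pos_frac = 0.3)
  m_rf <- fit_stacked(ds, stack_config(k = 3, seed = 2,
                                       meta_learner = "random-forest"))
  expect_equal(m_rf$meta$type, "random-forest")
  p <- predict(m_rf, ds)
  expect_true(all(p >= 0 & p <= 1))
  expect_error(normalized_meta_weights(m_rf), "not linear")
  m_sv <- fit_stacked(ds, stack_config(k = 3, seed = 2,
                                       meta_learner = "softvote"))
  expect_equal(unname(predict(m_sv, ds)),
               unname(soft_vote(base_probabilities(m_sv, ds))$scores))
})

test_that("stage failures carry stage context", {
  ds <- tiny_mv(n = 30, p_micro = 10, seed = 33, pos_frac = 0.2)
  expect_error(fit_stacked(ds, stack_config(k = 20, seed = 1)),
               "build_meta_features")
})

test_that("soft voting averages probabilities with ties to the negative class", {
  sv <- soft_vote(matrix(c(0.9, 0.8, 0.4), 1))
  expect_equal(sv$scores, 0.7)
  expect_equal(sv$labels, 1L)
  expect_equal(soft_vote(matrix(c(0.5, 0.5), 1))$labels, 0L)
  one <- soft_vote(matrix(c(0.2, 0.8, 0.51), 3))
  expect_equal(one$labels, as.integer(c(0.2, 0.8, 0.51) > 0.5))
  expect_error(soft_vote(matrix(numeric(0), 0, 0)), "empty")
})

test_that("equal-weight linear meta ranks samples exactly like soft voting", {
  set.seed(40)
  probs <- matrix(runif(60), 20, 3)
  sv <- soft_vote(probs)$scores
  # logistic(b0 + b * sum(p_j)) is a strictly monotone map of the mean
  lin <- plogis(-1.5 + 2 * rowSums(probs))
  expect_equal(order(lin), order(sv))
  labels <- rep(c(0L, 1L), 10)
  expect_equal(average_precision(labels, lin), average_precision(labels, sv))
})
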