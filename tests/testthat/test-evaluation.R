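test_that("average precision handles the canonical hand-worked cases", {
  # perfect ranking
  expect_equal(average_precision(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  # labels (1,0,1,0) scored (0.9,0.8,0.7,0.1): 0.5*1 + 0.5*(2/3)
  expect_equal(average_precision(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)),
               5 / 6, tolerance = 1e-12)
  # constant scores: a single threshold, precision = prevalence
  expect_equal(average_precision(c(1, 0, 0, 0, 1), rep(0.3, 5)), 2 / 5)
  expect_error(average_precision(c(0, 0, 0), c(1, 2, 3)), "no positive")
})

test_that("average precision matches the brute-force threshold oracle", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(5:30, 1)
    labels <- integer(n)
    labels[sample(n, sample(seq_len(n - 1), 1))] <- 1L
    # rounded scores introduce frequent ties
    scores <- round(runif(n), 1)
    expect_equal(average_precision(labels, scores),
                 ap_bruteforce(labels, scores), tolerance = 1e-12)
  }
})

test_that("average precision is invariant under strictly monotone transforms", {
  set.seed(55)
  labels <- rbinom(50, 1, 0.3)
  labels[1:2] <- c(0L, 1L)
  scores <- rnorm(50)
  ap <- average_precision(labels, scores)
  expect_equal(average_precision(labels, exp(scores)), ap)
  expect_equal(average_precision(labels, 3 * scores - 10), ap)
  expect_equal(average_precision(labels, rank(scores)), ap)
})

test_that("random-classifier AP equals the positive prevalence", {
  expect_equal(random_ap(c(rep(1L, 92), rep(0L, 443))), 92 / 535)
  expect_equal(round(random_ap(c(rep(1L, 92), rep(0L, 443))), 2), 0.17)
  expect_equal(round(random_ap(c(rep(1L, 119), rep(0L, 172))), 2), 0.41)
  expect_equal(random_ap(rep(c(0L, 1L), 10)), 0.5)
  expect_error(random_ap(rep(1L, 5)), "both classes")
})

test_that("MCC reproduces its defining identities and formula", {
  a <- c(1, 1, 0, 0, 1, 0)
  expect_equal(mcc(a, a), 1)
  expect_equal(mcc(a, 1 - a), -1)
  # TP=4, TN=3, FP=1, FN=2 -> 10 / sqrt(600)
  b <- c(rep(1, 4), rep(0, 3), rep(1, 1), rep(0, 2))
  aa <- c(rep(1, 4), rep(0, 3), rep(0, 1), rep(1, 2))
  expect_equal(mcc(aa, b), 10 / sqrt(600), tolerance = 1e-12)
  expect_equal(mcc(aa, b), mcc_from_counts(4, 3, 1, 2), tolerance = 1e-12)
  # zero-denominator convention
  expect_equal(mcc(a, rep(0, 6)), 0)
  expect_error(mcc(a, a[-1]), "length mismatch")
})

test_that("MCC agrees with the direct formula on random confusion tables", {
  set.seed(77)
  for (i in 1:100) {
    cts <- rmultinom(1, 40, runif(4, 0.05, 1))[, 1]  # TP TN FP FN
    a <- c(rep(1L, cts[1]), rep(0L, cts[2]), rep(0L, cts[3]), rep(1L, cts[4]))
    b <- c(rep(1L, cts[1]), rep(0L, cts[2]), rep(1L, cts[3]), rep(0L, cts[4]))
    expect_equal(mcc(a, b), mcc_from_counts(cts[1], cts[2], cts[3], cts[4]),
                 tolerance = 1e-12)
  }
})

test_that("MCC is symmetric and invariant to joint complementation", {
  set.seed(78)
  for (i in 1:20) {
    a <- rbinom(30, 1, 0.4); b <- rbinom(30, 1, 0.6)
    expect_equal(mcc(a, b), mcc(b, a))
    expect_equal(mcc(a, b), mcc(1 - a, 1 - b))
  }
})

test_that("the MCC matrix matches a hand-computed 4x4 on a 6-sample fixture", {
  labels <- c(1L, 1L, 0L, 0L, 1L, 0L)
  preds <- list(m1 = c(1L, 1L, 0L, 0L, 1L, 0L),   # identical to labels
                m2 = c(1L, 0L, 0L, 1L, 1L, 0L),
                m3 = c(0L, 0L, 0L, 0L, 0L, 0L))   # one-class predictor
  M <- mcc_matrix(preds, labels)
  expect_equal(dim(M), c(4, 4))
  expect_equal(M, t(M))
  vecs <- c(preds, list(Labels = labels))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    a <- vecs[[i]]; b <- vecs[[j]]
    expect_equal(M[i, j],
                 mcc_from_counts(sum(a & b), sum(!a & !b),
                                 sum(!a & b), sum(a & !b)),
                 tolerance = 1e-12)
  }
  expect_equal(M["m1", "Labels"], 1)
  expect_equal(M["m3", "Labels"], 0)   # all-negative vs labels: convention 0
  expect_equal(M["m3", "m3"], 0)       # single-class diagonal is undefined -> 0
  expect_equal(M["m1", "m1"], 1)
})

test_that("cv_performance of a constant scorer is analytic", {
  ds <- micro_only(tiny_mv(n = 40, p_micro = 10, seed = 41, pos_frac = 0.3))
  cfg <- stack_config(k = 4, seed = 6, specs = list(
    base_learner_spec("DUMMY", "dummy-prevalence", "microbial")))
  cv <- cv_performance(ds, cfg, include_stacked = FALSE)
  folds <- stratified_folds(ds$labels, 4, mvstack:::derive_seed(6, 5L))
  for (f in 1:4) {
    row <- cv$folds[cv$folds$fold == f & cv$folds$model == "DUMMY", ]
    expect_equal(row$train_ap, mean(ds$labels[folds != f]))
    expect_equal(row$validation_ap, mean(ds$labels[folds == f]))
  }
  g <- overfit_gap(cv, cfg$specs)
  expect_equal(g$gap[g$model == "DUMMY"],
               median(cv$folds$train_ap[cv$folds$model == "DUMMY"]) -
                 median(cv$folds$validation_ap[cv$folds$model == "DUMMY"]))
})

test_that("capable learners reach validation AP 1 on cleanly separable data", {
  ds <- micro_only(generate_multiview(synthetic_config(
    n_samples = 60, positive_fraction = 0.4, n_microbial = 30,
    n_informative_microbial = 8, microbial_effect = 5, sparsity = 0,
    seed = 42)))
  cfg <- stack_config(k = 3, seed = 2, specs = list(
    base_learner_spec("SGD_LL", "sgd-logistic", "microbial", seed = 1),
    base_learner_spec("RF", "random-forest", "microbial", seed = 1)))
  cv <- cv_performance(ds, cfg, include_stacked = FALSE)
  meds <- cv$medians
  expect_equal(meds$median_validation_ap[meds$model == "SGD_LL"], 1)
  expect_equal(meds$median_validation_ap[meds$model == "RF"], 1)
})

test_that("a memorizing learner shows a large overfit gap on pure noise", {
  ds <- micro_only(generate_multiview(synthetic_config(
    n_samples = 60, positive_fraction = 0.3, n_microbial = 40,
    n_informative_microbial = 0, microbial_effect = 0,
    clinical_effect = 0, sparsity = 0.3, seed = 43)))
  cfg <- stack_config(k = 3, seed = 4, alpha = 1, correction = "none",
                      specs = list(base_learner_spec(
                        "RF", "random-forest", "microbial", seed = 1)))
  cv <- cv_performance(ds, cfg, include_stacked = FALSE)
  g <- overfit_gap(cv, cfg$specs)
  expect_gt(g$gap[g$model == "RF"], 0.2)
})

test_that("evaluate_stacked reports every model on both splits coherently", {
  ds <- tiny_mv(n = 70, p_micro = 40, seed = 44, pos_frac = 0.3)
  sp <- split_train_test(ds, 0.25, seed = 3)
  m <- fit_stacked(sp$train, stack_config(k = 3, seed = 3))
  ev <- evaluate_stacked(m, sp$train, sp$test)
  want <- c("SGD_LL", "SGD_HL", "KNN", "MLP", "QDA", "RF", "HGBC_otu",
            "HGBC_clin", "SoftVote", "Stacked")
  for (s in c("train", "test")) {
    expect_setequal(ev$ap$model[ev$ap$split == s], want)
  }
  expect_true(all(ev$ap$ap >= 0 & ev$ap$ap <= 1))
  expect_equal(ev$random_ap[["train"]], mean(sp$train$labels))
  expect_equal(ev$random_ap[["test"]], mean(sp$test$labels))
  M <- ev$mcc$test
  expect_equal(M, t(M))
  expect_true(all(M >= -1 & M <= 1))
  # recall non-decreasing along each PR curve
  for (cv in ev$pr_curves$test) {
    expect_true(all(diff(cv$recall) >= 0))
  }
})
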