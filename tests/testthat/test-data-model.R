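test_that("load_multiview joins by id, maps labels and preserves missingness", {
  dir <- withr::local_tempdir()
  clin <- data.frame(sample_id = c("a", "b", "c", "d"),
                     age = c(10, NA, 12, 14),
                     sex = c("F", "M", "M", "F"),
                     diagnosis = c("CD", "UC", "CD", "UC"))
  micr <- data.frame(sample_id = c("d", "c", "b", "a"),
                     otu1 = c(0, 1.5, 2, 0), otu2 = c(3, 0, 0, 1))
  data.table::fwrite(clin, file.path(dir, "clin.csv"), na = "")
  data.table::fwrite(micr, file.path(dir, "micr.csv"))
  ds <- load_multiview(file.path(dir, "clin.csv"), file.path(dir, "micr.csv"),
                       label_column = "diagnosis", positive_label = "UC",
                       categorical = "sex")
  expect_equal(ds$labels, c(0L, 1L, 0L, 1L))
  expect_equal(ds$sample_ids, c("a", "b", "c", "d"))
  # rows re-aligned by id across tables
  expect_equal(unname(ds$views$microbial[, "otu1"]), c(0, 2, 1.5, 0))
  # missing value preserved, never imputed
  expect_true(is.na(ds$views$clinical$age[2]))
  expect_s3_class(ds$views$clinical$sex, "factor")
  meta <- ds$feature_meta
  expect_equal(meta$kind[meta$feature == "sex"], "categorical")
})

test_that("load_multiview rejects malformed inputs", {
  dir <- withr::local_tempdir()
  w <- function(df, f) {
    data.table::fwrite(df, file.path(dir, f)); file.path(dir, f)
  }
  c1 <- w(data.frame(sample_id = c("a", "b", "c", "d", "e"),
                     x = 1:5, y = c("A", "B", "A", "B", "A")), "c1.csv")
  m1 <- w(data.frame(sample_id = c("p", "q", "r", "s", "t"), o = 1:5), "m1.csv")
  expect_error(load_multiview(c1, m1, "y", "B"), "no overlapping")
  m2 <- w(data.frame(sample_id = c("a", "a", "b", "c", "d"), o = 1:5), "m2.csv")
  expect_error(load_multiview(c1, m2, "y", "B"), "duplicate")
  c3 <- w(data.frame(sample_id = c("a", "b", "c", "d", "e"),
                     x = 1:5, y = c("A", "B", "C", "A", "B")), "c3.csv")
  m3 <- w(data.frame(sample_id = c("a", "b", "c", "d", "e"), o = 1:5), "m3.csv")
  expect_error(load_multiview(c3, m3, "y", "B"), "more than 2")
  # label column in neither table
  expect_error(load_multiview(c1, m3, "zz", "B"), "exactly one table")
})

test_that("write then load round-trips values, order and missingness exactly", {
  ds <- tiny_mv(n = 25, p_micro = 8, seed = 3)
  dir <- withr::local_tempdir()
  write_multiview(ds, dir)
  ds2 <- load_multiview(file.path(dir, "clinical.csv"),
                        file.path(dir, "microbial.csv"),
                        label_column = "label", positive_label = 1,
                        categorical = grep("cat", colnames(ds$views$clinical),
                                           value = TRUE))
  expect_identical(ds2$sample_ids, ds$sample_ids)
  expect_identical(ds2$labels, ds$labels)
  expect_identical(colnames(ds2$views$microbial), colnames(ds$views$microbial))
  expect_identical(unname(ds2$views$microbial), unname(ds$views$microbial))
  expect_identical(is.na(ds2$views$clinical), is.na(ds$views$clinical))
  num <- vapply(ds$views$clinical, is.numeric, logical(1))
  expect_identical(ds2$views$clinical[num], ds$views$clinical[num])
})

test_that("multiview_dataset enforces its invariants", {
  ds <- tiny_mv(n = 20, p_micro = 5, seed = 1)
  expect_error(multiview_dataset(ds$views, ds$labels[-1], ds$sample_ids),
               "one entry per sample")
  expect_error(multiview_dataset(ds$views, rep(0L, 20), ds$sample_ids),
               "both classes")
  bad <- ds$views
  bad$microbial[1, 1] <- -1
  expect_error(multiview_dataset(bad, ds$labels, ds$sample_ids),
               "non-negative")
  expect_error(multiview_dataset(ds$views, ds$labels,
                                 rep("s1", 20)), "duplicate")
})

test_that("stratified split matches the cohort-count allocation rule", {
  # 535 samples with 92 positives at fraction 0.2:
  # round(92 * .2) + round(443 * .2) = 18 + 89 = 107 test samples
  labs <- c(rep(1L, 92), rep(0L, 443))
  micro <- matrix(rexp(535 * 4), 535, 4,
                  dimnames = list(NULL, paste0("o", 1:4)))
  ds <- multiview_dataset(list(microbial = micro), labs, sprintf("s%03d", 1:535))
  sp <- split_train_test(ds, 0.2, seed = 11)
  expect_equal(length(sp$test$sample_ids), 107)
  expect_equal(sum(sp$test$labels), 18)
  # partition: disjoint, union = original
  expect_length(intersect(sp$train$sample_ids, sp$test$sample_ids), 0)
  expect_setequal(c(sp$train$sample_ids, sp$test$sample_ids), ds$sample_ids)
  # per-class proportions within one sample of 92/535
  expect_lt(abs(sum(sp$test$labels) - 92 * 0.2), 1)
  expect_lt(abs(sum(sp$train$labels) - 92 * 0.8), 1)
})

test_that("split is deterministic per seed and varies across seeds", {
  ds <- tiny_mv(n = 100, p_micro = 5, seed = 2)
  s1 <- split_train_test(ds, 0.2, seed = 5)
  s2 <- split_train_test(ds, 0.2, seed = 5)
  expect_identical(s1$test$sample_ids, s2$test$sample_ids)
  s3 <- split_train_test(ds, 0.2, seed = 6)
  expect_false(identical(s1$test$sample_ids, s3$test$sample_ids))
  # unstratified mode also partitions
  s4 <- split_train_test(ds, 0.2, seed = 5, stratify = FALSE)
  expect_setequal(c(s4$train$sample_ids, s4$test$sample_ids), ds$sample_ids)
})

test_that("split rejects classes too small to stratify", {
  labs <- c(1L, rep(0L, 9))
  micro <- matrix(runif(10 * 3), 10, 3, dimnames = list(NULL, paste0("o", 1:3)))
  ds <- multiview_dataset(list(microbial = micro), labs, paste0("s", 1:10))
  expect_error(split_train_test(ds, 0.2, seed = 1), ">= 2 samples")
})

test_that("dropping leakage features removes them everywhere", {
  ds <- tiny_mv(n = 20, p_micro = 6, seed = 4)
  ds2 <- mv_drop_features(ds, c("clin_num_01", "otu_0001"))
  expect_false("clin_num_01" %in% colnames(ds2$views$clinical))
  expect_false("otu_0001" %in% colnames(ds2$views$microbial))
  expect_false(any(c("clin_num_01", "otu_0001") %in% ds2$feature_meta$feature))
})
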