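test_that("featurization is deterministic, one-hot over variable positions only", {
  sc <- uk18_scaffold()
  spec <- feature_spec()
  s1 <- "ACSRYEVDCRGRGSACG"
  s2 <- "ACDRFVVDCRGRGGPCG"
  x <- featurize(c(s1, s2, s1), sc, spec)
  expect_identical(x[1, ], x[3, ])
  oh_cols <- grepl("^pos[0-9]+_", colnames(x))
  expect_equal(sum(oh_cols), 12 * 20)  # 12 variable positions x q
  expect_equal(unname(rowSums(x[, oh_cols])), c(12, 12, 12))
  # sequences identical at variable positions have identical vectors even if
  # built in different calls
  y <- featurize(s1, sc, spec)
  expect_identical(unname(x[1, ]), unname(y[1, ]))
  expect_error(feature_spec(descriptors = "logP"), "unknown descriptor")
})

test_that("the additive charge model counts D/E as -1 and K/R as +1, H as 0", {
  sc <- scaffold(6, list(`1` = "C"), name = "loop")
  spec <- feature_spec(use_onehot = FALSE,
                       descriptors = c("net_charge_pH7.4", "proline_count",
                                       "aromatic_count"))
  x <- featurize("CRRDHG", sc, spec)
  expect_equal(unname(x[1, "net_charge_pH7.4"]), 1)  # 2 Arg + 1 Asp
  expect_equal(unname(x[1, "proline_count"]), 0)
  x2 <- featurize("CWYFPP", sc, spec)
  expect_equal(unname(x2[1, "aromatic_count"]), 3)
  expect_equal(unname(x2[1, "proline_count"]), 2)
})

test_that("molecular weight sums residue masses plus one water", {
  sc <- scaffold(2, list(), name = "di")
  spec <- feature_spec(use_onehot = FALSE, descriptors = "molecular_weight")
  # Gly-Gly: 2 x 57.0519 + 18.0153
  expect_equal(unname(featurize("GG", sc, spec)[1, 1]), 132.1191,
               tolerance = 1e-6)
})

test_that("a deep forest interpolates an exact one-hot function of the sequence", {
  sc <- free_scaffold(L = 6, q = 4)
  set.seed(31)
  seqs <- unique(replicate(60, random_conformant(sc)))[1:40]
  # y depends only on the residue at position 2
  y_nM <- 10^(as.integer(substr(seqs, 2, 2) == "A") + 1)
  rec <- affinity_records(sprintf("r%d", seq_along(seqs)), seqs, y_nM, sc,
                          ki_unit = "nM")
  # the two-level target triggers a "regression?" caution from the forest;
  # that is exactly the interpolation setting being tested
  fit <- suppressWarnings(
    fit_regressor(rec, sc, config = regressor_config(n_trees = 300, seed = 1)))
  expect_lt(fit$report$train_rmse, 0.25)
  expect_gte(fit$report$cv_rmse, 0)
  # training points are recovered nearly exactly
  pred <- predict_ki(fit, rec$sequence)
  expect_lt(sqrt(mean((log10(pred) - log10(rec$ki))^2)), 0.3)
})

test_that("pure-noise targets show the overfitting gap", {
  sc <- free_scaffold(L = 6, q = 4)
  set.seed(37)
  seqs <- unique(replicate(50, random_conformant(sc)))[1:30]
  rec <- affinity_records(sprintf("r%d", seq_along(seqs)), seqs,
                          10^rnorm(30, 2, 0.7), sc, ki_unit = "nM")
  fit <- fit_regressor(rec, sc, config = regressor_config(seed = 2))
  expect_gt(fit$report$overfit_gap, 0)
  expect_gte(fit$report$cv_rmse, fit$report$train_rmse)
})

test_that("more training data improves generalization on the planted landscape", {
  bm <- synthetic_family_benchmark()
  ls <- bm$landscape
  sc <- bm$scaffold
  set.seed(41)
  pool <- unique(replicate(500, random_conformant(sc)))
  train30 <- observe_ki(ls, pool[1:30], seed = 42)
  train200 <- observe_ki(ls, pool[1:200], seed = 42)
  f30 <- fit_regressor(train30, sc, config = regressor_config(seed = 3))
  f200 <- fit_regressor(train200, sc, config = regressor_config(seed = 3))
  expect_lt(f200$report$cv_rmse, f30$report$cv_rmse)
  # held-out rank correlation exceeds 0.5 at n = 200
  held <- pool[201:300]
  truth <- true_log10_ki(ls, held)
  pred <- log10(predict_ki(f200, held))
  expect_gt(cor(pred, truth, method = "spearman"), 0.5)
})

test_that("predictions are positive, stateless, and spec-checked", {
  sc <- free_scaffold(L = 5, q = 4)
  set.seed(43)
  seqs <- unique(replicate(30, random_conformant(sc)))[1:20]
  rec <- affinity_records(sprintf("r%d", 1:20), seqs, 10^rnorm(20, 2, 0.5),
                          sc, ki_unit = "nM")
  fit <- fit_regressor(rec, sc, config = regressor_config(seed = 5))
  new <- replicate(10, random_conformant(sc))
  p <- predict_ki(fit, new)
  expect_true(all(p > 0))
  expect_equal(predict_ki(fit, rev(new)), rev(p))
  fit_small <- fit_regressor(rec, sc,
                             spec = feature_spec(descriptors = "net_charge_pH7.4"),
                             config = regressor_config(seed = 5))
  fit_small$spec <- feature_spec()  # corrupt the spec: length now mismatches
  expect_error(predict_ki(fit_small, new), "feature mismatch")
})

test_that("the regressor is run-to-run deterministic at a fixed seed", {
  rec <- uk_mini_records()
  sc <- uk18_scaffold()
  f1 <- suppressWarnings(
    fit_regressor(rec, sc, config = regressor_config(n_trees = 100, seed = 9)))
  f2 <- suppressWarnings(
    fit_regressor(rec, sc, config = regressor_config(n_trees = 100, seed = 9)))
  new <- replicate(5, random_conformant(sc))
  expect_identical(predict_ki(f1, new), predict_ki(f2, new))
  expect_identical(f1$report, f2$report)
})

test_that("percentile threshold follows the linear-interpolation convention", {
  expect_equal(percentile_threshold(c(1, 2, 3, 4), 50), 2.5)
  expect_equal(percentile_threshold(7, 30), 7)
  expect_equal(percentile_threshold(seq(0.1, 1, by = 0.1), 50), 0.55)
  expect_equal(percentile_threshold(c(3, 1, 2), 50), median(c(1, 2, 3)))
  expect_error(percentile_threshold(numeric(0), 50), "empty")
  expect_error(percentile_threshold(1:3, 0), "\\(0, 100\\]")
})

test_that("threshold filtering is strict and order-preserving", {
  pred <- c(0.5, 0.92, 1.3) * 1e-6
  out <- filter_by_threshold(c("a", "b", "c"), pred, 0.92e-6)
  expect_equal(out$sequence, "a")
  expect_equal(attr(out, "fraction"), 1 / 3)
  expect_equal(nrow(filter_by_threshold("a", 1, 0.5)), 0)
  all_kept <- filter_by_threshold(c("a", "b"), c(1, 2), 5)
  expect_equal(all_kept$sequence, c("a", "b"))
  expect_error(filter_by_threshold(c("a", "b"), 1, 2), "length")
  # the strict median rule keeps floor(n/2) of distinct values
  v <- c(10, 20, 30, 40)
  kept <- filter_by_threshold(letters[1:4], v, percentile_threshold(v, 50))
  expect_equal(nrow(kept), 2)
  v5 <- c(10, 20, 30, 40, 50)
  kept5 <- filter_by_threshold(letters[1:5], v5, percentile_threshold(v5, 50))
  expect_equal(nrow(kept5), 2)
})
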