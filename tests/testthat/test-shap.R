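# Gradient-boosted classifier, repeated-CV SHAP aggregation, and the
# holdout metrics.

test_that("stratified split allocates test samples by class rounding", {
  labels <- setNames(rep(c("sensitive", "resistant"), c(60, 55)),
                     sprintf("s%03d", 1:115))
  sp <- stratified_split(labels, 0.2, seed = 3)
  expect_equal(sum(labels[sp$test] == "sensitive"), 12)
  expect_equal(sum(labels[sp$test] == "resistant"), 11)
  expect_setequal(c(sp$train, sp$test), names(labels))
  expect_identical(sp$test, stratified_split(labels, 0.2, seed = 3)$test)
  expect_false(identical(sp$test, stratified_split(labels, 0.2, 4)$test))
  expect_error(stratified_split(labels, 0), "fraction_test")
})

test_that("classifier nails a separating feature and rejects bad input", {
  fx <- make_feature_fixture(n_per_class = 30, n_inf = 1, n_noise = 20,
                             effect = 10, seed = 1)
  model <- train_gbdt(fx$features, fx$labels, seed = 1)
  m <- evaluate_holdout(model, fx$features, fx$labels)
  expect_equal(m$roc_auc, 1.0)
  expect_error(train_gbdt(fx$features,
                          setNames(rep("resistant", 60), names(fx$labels)),
                          seed = 1),
               "single class")
})

test_that("permuted labels leave holdout performance at chance", {
  aucs <- sapply(1:20, function(s) {
    fx <- make_feature_fixture(n_per_class = 40, n_inf = 0, n_noise = 60,
                               seed = s)
    sp <- stratified_split(fx$labels, 0.25, seed = s)
    model <- train_gbdt(fx$features[, sp$train], fx$labels[sp$train],
                        seed = s)
    evaluate_holdout(model, fx$features[, sp$test],
                     fx$labels[sp$test])$roc_auc
  })
  expect_equal(mean(aucs), 0.5, tolerance = 0.1)
})

test_that("one informative gene among many noise genes tops attribution", {
  fx <- make_feature_fixture(n_per_class = 40, n_inf = 1, n_noise = 500,
                             effect = 3, seed = 2)
  sh <- shap_repeated_cv(fx$features, fx$labels, n_repeats = 2)
  expect_equal(sh$summary$gene[sh$summary$rank == 1], fx$informative)
})

test_that("per-sample attributions sum to the model margin", {
  fx <- make_feature_fixture(n_per_class = 30, n_inf = 3, n_noise = 100,
                             effect = 1.5, seed = 3)
  model <- train_gbdt(fx$features, fx$labels, seed = 1)
  contrib <- predict(model, fx$features, type = "contrib")
  margin <- predict(model, fx$features, type = "margin")
  expect_lt(max(abs(rowSums(contrib) - margin)), 1e-6)
})

test_that("repeated-CV SHAP is deterministic and order-invariant", {
  fx <- make_feature_fixture(n_per_class = 20, n_inf = 2, n_noise = 40,
                             effect = 2, seed = 4)
  sh1 <- shap_repeated_cv(fx$features, fx$labels, n_repeats = 2)
  sh2 <- shap_repeated_cv(fx$features, fx$labels, n_repeats = 2)
  expect_identical(sh1$summary, sh2$summary)
  perm <- sample(ncol(fx$features))
  sh3 <- shap_repeated_cv(fx$features[, perm], fx$labels, n_repeats = 2)
  expect_equal(sh1$summary, sh3$summary, tolerance = 1e-12)
  expect_equal(ncol(sh1$per_repeat), 2)
  expect_true(all(sh1$summary$mean_abs_shap >= 0))
  expect_setequal(sh1$summary$rank, seq_len(nrow(sh1$summary)))
})

test_that("constant features receive exactly zero attribution", {
  fx <- make_feature_fixture(n_per_class = 20, n_inf = 2, n_noise = 30,
                             effect = 2, seed = 5)
  fx$features["g010", ] <- 3.14
  sh <- shap_repeated_cv(fx$features, fx$labels, n_repeats = 1)
  expect_identical(sh$summary$mean_abs_shap[sh$summary$gene == "g010"], 0)
})

test_that("contributing-gene selection uses a strict threshold", {
  s <- structure(list(summary = data.frame(
    gene = c("a", "b", "c"), mean_abs_shap = c(0, 0.01, 0.5),
    rank = c(3, 2, 1))), class = "shap_summary")
  expect_setequal(contributing_genes(s), c("b", "c"))
  expect_equal(contributing_genes(s, epsilon = 0.01), "c")
  s$summary$mean_abs_shap <- 0
  expect_equal(length(contributing_genes(s)), 0)
})

test_that("ROC and PR AUC match brute-force oracles", {
  # pair-counting example: 3 of 4 positive-negative pairs ordered
  scores <- c(0.9, 0.8, 0.3, 0.1)
  pos <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(roc_auc(scores, pos), 0.75)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(TRUE, TRUE, FALSE, FALSE)), 1)
  # constant scores fall back to the diagonal
  expect_equal(roc_auc(rep(0.5, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  set.seed(7)
  for (i in 1:10) {
    n <- sample(10:200, 1)
    s <- round(runif(n), 2)  # force ties
    y <- runif(n) > 0.4
    if (!any(y) || all(y)) next
    expect_equal(roc_auc(s, y), oracle_roc_auc(s, y), tolerance = 1e-9)
    expect_equal(pr_auc(s, y), oracle_pr_auc(s, y), tolerance = 1e-9)
  }
  skip_if_not_installed("pROC")
  set.seed(8)
  s <- runif(80); y <- runif(80) > 0.5
  expect_equal(roc_auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              levels = c(FALSE, TRUE),
                                              direction = "<"))),
               tolerance = 1e-9)
})

test_that("holdout evaluation reports confusion and degenerate cases", {
  fx <- make_feature_fixture(n_per_class = 15, n_inf = 1, n_noise = 10,
                             effect = 10, seed = 9)
  model <- train_gbdt(fx$features, fx$labels, seed = 1)
  m <- evaluate_holdout(model, fx$features, fx$labels)
  expect_equal(sum(m$confusion), 30)
  expect_gte(m$accuracy, 0.85)
  # single-class test set: AUCs undefined, reported as NA
  sen <- names(fx$labels)[fx$labels == "sensitive"]
  m2 <- evaluate_holdout(model, fx$features[, sen], fx$labels[sen])
  expect_true(is.na(m2$roc_auc))
})
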