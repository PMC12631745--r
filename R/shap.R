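# Gradient-boosted classification of the phenotype from log TPM features
# and per-gene SHAP attribution magnitudes aggregated over repeated
# stratified cross-validation. The booster is trained with AUC-based
# early stopping on a held-out slice of the training samples; SHAP values
# are the exact tree attributions, computed for held-out-fold samples
# only so the attribution ranking is not optimistic.

default_gbdt_params <- function() {
  list(max_depth = 8, eta = 0.1, alpha = 0.1, lambda = 0.1,
       colsample_bytree = 0.3, nrounds = 150, early_stopping_rounds = 50,
       validation_fraction = 0.2, nthread = 1)
}

#' Stratified train/test split
#'
#' Allocates `round(class_size * fraction_test)` samples of each class to
#' the test set, sampling within sorted ids so the split depends only on
#' `(labels, fraction_test, seed)` and not on input order.
#'
#' @param labels Named character class vector
#'   (`"resistant"`/`"sensitive"`).
#' @param fraction_test Test fraction in (0, 1).
#' @param seed Integer seed.
#' @return List of class `split_spec`: `train`, `test` (character ids),
#'   `fraction_test`, `seed`.
#' @export
stratified_split <- function(labels, fraction_test = 0.2, seed = 1) {
  check_binary_labels(labels)
  if (!is.numeric(fraction_test) || fraction_test <= 0 || fraction_test >= 1) {
    stop("fraction_test must be in (0, 1)")
  }
  classes <- split(sort(names(labels)), labels[sort(names(labels))])
  if (any(vapply(classes, length, 1L) < 2)) {
    stop("each class needs >= 2 samples")
  }
  test <- with_seed(seed, {
    unlist(lapply(classes, function(ids) {
      n_test <- round(length(ids) * fraction_test)
      sample(ids, n_test)
    }), use.names = FALSE)
  })
  structure(list(train = sort(setdiff(names(labels), test)),
                 test = sort(test),
                 fraction_test = fraction_test, seed = seed),
            class = "split_spec")
}

#' Train a gradient-boosted tree classifier
#'
#' Binary xgboost classifier (logistic objective, AUC metric) on
#' log-TPM features, with early stopping against a stratified validation
#' slice carved out of the training samples. Single-threaded with seeded
#' feature subsampling, so training is deterministic given the inputs and
#' seed.
#'
#' @param features Gene x sample numeric matrix.
#' @param labels Named character class vector covering the samples.
#' @param params Hyperparameters; defaults: `max_depth = 8`, `eta = 0.1`,
#'   `alpha = 0.1` (L1), `lambda = 0.1` (L2), `colsample_bytree = 0.3`
#'   (per-tree feature subsampling, the overfitting control that also
#'   lets attribution survey redundant informative genes), `nrounds =
#'   150` cap, `early_stopping_rounds = 50`, `validation_fraction = 0.2`.
#' @param seed Seed for the validation slice.
#' @return Object of class `gbdt_classifier` wrapping the booster.
#' @export
train_gbdt <- function(features, labels, params = list(), seed = 1) {
  check_binary_labels(labels)
  ids <- colnames(features)
  if (!all(ids %in% names(labels))) stop("labels must cover all samples")
  lab <- labels[ids]
  if (length(unique(lab)) < 2) stop("training labels contain a single class")
  if (any(table(lab) < 2)) stop("each class needs >= 2 training samples")
  p <- utils::modifyList(default_gbdt_params(), params)

  val <- stratified_split(lab, p$validation_fraction, seed)$test
  tr <- setdiff(ids, val)
  if (length(unique(lab[tr])) < 2 || length(unique(lab[val])) < 2) {
    stop("early-stopping slice left a single-class set; add samples")
  }
  X <- t(features)
  y <- as.integer(lab == .positive_class)
  names(y) <- ids
  dtrain <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = y[tr])
  dval <- xgboost::xgb.DMatrix(X[val, , drop = FALSE], label = y[val])
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", eval_metric = "auc",
                  max_depth = p$max_depth, eta = p$eta,
                  alpha = p$alpha, lambda = p$lambda,
                  colsample_bytree = p$colsample_bytree,
                  seed = as.integer(seed) %% .Machine$integer.max,
                  nthread = p$nthread, tree_method = "hist"),
    data = dtrain, nrounds = p$nrounds,
    evals = list(val = dval),
    early_stopping_rounds = p$early_stopping_rounds, verbose = 0)
  structure(list(booster = booster, genes = rownames(features),
                 train_ids = tr, validation_ids = val,
                 params = p, seed = seed),
            class = "gbdt_classifier")
}

#' Predict from a gradient-boosted classifier
#'
#' @param object A `gbdt_classifier`.
#' @param newdata Gene x sample matrix with the training genes.
#' @param type `"prob"` (resistant-class probability), `"margin"` (raw
#'   log-odds), or `"contrib"` (per-feature SHAP attributions plus the
#'   expected-value column `(Intercept)`; rows sum to the margin).
#' @param ... Unused.
#' @return Numeric vector (named by sample) or, for `"contrib"`, a
#'   samples x (genes + intercept) matrix.
#' @export
predict.gbdt_classifier <- function(object, newdata,
                                    type = c("prob", "margin", "contrib"),
                                    ...) {
  type <- match.arg(type)
  miss <- setdiff(object$genes, rownames(newdata))
  if (length(miss) > 0) {
    stop("newdata lacks genes: ", paste(head(miss, 5), collapse = ", "))
  }
  X <- t(newdata[object$genes, , drop = FALSE])
  dm <- xgboost::xgb.DMatrix(X)
  out <- switch(type,
    prob = predict(object$booster, dm),
    margin = predict(object$booster, dm, outputmargin = TRUE),
    contrib = predict(object$booster, dm, predcontrib = TRUE))
  if (type == "contrib") {
    rownames(out) <- colnames(newdata)
  } else {
    names(out) <- colnames(newdata)
  }
  out
}

#' @export
print.gbdt_classifier <- function(x, ...) {
  cat("Gradient-boosted phenotype classifier:",
      length(x$train_ids), "training samples,",
      length(x$genes), "gene features, best iteration",
      xgboost::xgb.attr(x$booster, "best_iteration"), "\n")
  invisible(x)
}

#' SHAP attribution summary over repeated stratified cross-validation
#'
#' For each of `n_repeats` repeats (seeded `base_seed + r`), partitions
#' the samples into `n_folds` stratified folds, trains the booster on
#' each training fold and computes exact SHAP attributions for the
#' held-out fold. The per-repeat summary is the mean absolute attribution
#' per gene over all held-out samples; the final `mean_abs_shap` averages
#' the repeats. Samples are ordered by id internally, so the result is
#' invariant to input column order.
#'
#' @param features Gene x sample log-TPM matrix.
#' @param labels Named character class vector.
#' @param n_repeats Number of CV repeats (default 12).
#' @param n_folds Folds per repeat (default 5).
#' @param base_seed Base seed (default 42).
#' @param params Booster hyperparameters, as in [train_gbdt()].
#' @return Object of class `shap_summary`: `summary` (data frame `gene`,
#'   `mean_abs_shap`, `rank`), `per_repeat` (gene x repeat matrix),
#'   `n_repeats`, `n_folds`, `base_seed`.
#' @export
shap_repeated_cv <- function(features, labels, n_repeats = 12, n_folds = 5,
                             base_seed = 42, params = list()) {
  check_binary_labels(labels)
  ids <- sort(colnames(features))
  features <- features[, ids, drop = FALSE]
  lab <- labels[ids]
  genes <- rownames(features)
  per_repeat <- matrix(NA_real_, nrow = length(genes), ncol = n_repeats,
                       dimnames = list(genes, paste0("repeat_", seq_len(n_repeats))))
  for (r in seq_len(n_repeats)) {
    seed_r <- base_seed + r
    fold <- stratified_folds(lab, n_folds, seed_r)
    abs_sum <- numeric(length(genes))
    n_explained <- 0L
    for (f in seq_len(n_folds)) {
      tr <- names(fold)[fold != f]
      te <- names(fold)[fold == f]
      model <- train_gbdt(features[, tr, drop = FALSE], lab[tr],
                          params = params, seed = seed_r * n_folds + f)
      contrib <- predict(model, features[, te, drop = FALSE],
                         type = "contrib")
      abs_sum <- abs_sum + colSums(abs(contrib[, genes, drop = FALSE]))
      n_explained <- n_explained + length(te)
    }
    per_repeat[, r] <- abs_sum / n_explained
  }
  mean_abs <- rowMeans(per_repeat)
  summary <- data.frame(gene = genes, mean_abs_shap = mean_abs,
                        rank = rank(-mean_abs, ties.method = "first"),
                        row.names = NULL)
  structure(list(summary = summary, per_repeat = per_repeat,
                 n_repeats = n_repeats, n_folds = n_folds,
                 base_seed = base_seed),
            class = "shap_summary")
}

#' @export
print.shap_summary <- function(x, ...) {
  top <- x$summary[order(x$summary$rank), ][1:min(5, nrow(x$summary)), ]
  cat("SHAP summary over", x$n_repeats, "x", x$n_folds,
      "fold cross-validation;", sum(x$summary$mean_abs_shap > 0),
      "of", nrow(x$summary), "genes contribute\n  top genes:",
      paste(top$gene, collapse = ", "), "\n")
  invisible(x)
}

#' Genes with non-trivial SHAP contribution
#'
#' @param summary A `shap_summary`.
#' @param epsilon Strict lower bound on `mean_abs_shap` (default 0).
#' @return Character vector of gene ids.
#' @export
contributing_genes <- function(summary, epsilon = 0) {
  stopifnot(inherits(summary, "shap_summary"))
  summary$summary$gene[summary$summary$mean_abs_shap > epsilon]
}

#' Holdout classification metrics
#'
#' Accuracy and confusion at probability cutoff 0.5, with ROC and
#' precision-recall AUCs by trapezoidal integration over all score
#' thresholds. Undefined AUCs (single-class test set) are `NA`.
#'
#' @param classifier A fitted classifier with a `predict` method
#'   returning resistant-class probabilities (e.g. `gbdt_classifier` or
#'   `signature_model`).
#' @param features Gene x sample matrix of test samples.
#' @param labels Named character class vector for the test samples.
#' @return List of class `holdout_metrics`: `accuracy`, `roc_auc`,
#'   `pr_auc`, `confusion` (2x2 counts), `scores`.
#' @export
evaluate_holdout <- function(classifier, features, labels) {
  check_binary_labels(labels)
  if (ncol(features) == 0) stop("empty test set")
  scores <- predict(classifier, features)
  lab <- labels[colnames(features)]
  cm <- confusion_metrics(scores, lab, cutoff = 0.5)
  structure(list(accuracy = cm$accuracy,
                 roc_auc = roc_auc(scores, lab),
                 pr_auc = pr_auc(scores, lab),
                 confusion = matrix(c(cm$tp, cm$fn, cm$fp, cm$tn), 2, 2,
                                    dimnames = list(
                                      predicted = c("resistant", "sensitive"),
                                      truth = c("resistant", "sensitive"))),
                 scores = scores),
            class = "holdout_metrics")
}

#' @export
print.holdout_metrics <- function(x, ...) {
  cat(sprintf("Holdout metrics: accuracy %.3f, ROC AUC %s, PR AUC %s\n",
              x$accuracy,
              ifelse(is.na(x$roc_auc), "NA", sprintf("%.3f", x$roc_auc)),
              ifelse(is.na(x$pr_auc), "NA", sprintf("%.3f", x$pr_auc))))
  print(x$confusion)
  invisible(x)
}

#' Write a SHAP summary as delimited text
#'
#' @param summary A `shap_summary`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_shap_summary <- function(summary, path) {
  stopifnot(inherits(summary, "shap_summary"))
  df <- cbind(summary$summary, summary$per_repeat)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
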