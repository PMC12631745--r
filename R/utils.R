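# Internal helpers shared across stages: seeded evaluation, stratified
# partitions, binary-classification metrics, and the ridge-logistic solver
# used by the elimination and signature stages.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the Mersenne-Twister stream seeded at `seed`, then
#' restores the caller's RNG state, so every generator in the package is a
#' pure function of its arguments.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

# Binary labels are handled as character vectors with the positive class
# "resistant" and negative class "sensitive" throughout.
.positive_class <- "resistant"
.negative_class <- "sensitive"

check_binary_labels <- function(labels) {
  if (is.null(names(labels))) stop("labels must be a named vector (names = sample ids)")
  bad <- setdiff(unique(labels), c(.positive_class, .negative_class))
  if (length(bad) > 0) {
    stop("labels must be '", .positive_class, "' or '", .negative_class,
         "'; found: ", paste(bad, collapse = ", "))
  }
  invisible(labels)
}

#' Stratified fold assignment
#'
#' Assigns samples to `k` cross-validation folds, stratified by class so
#' fold class proportions track the cohort. Samples are processed in sorted
#' id order before the seeded shuffle, so the assignment is invariant to
#' the order in which samples are supplied.
#'
#' @param labels Named character vector of class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Named integer vector of fold indices in 1..k.
#' @keywords internal
stratified_folds <- function(labels, k, seed) {
  check_binary_labels(labels)
  classes <- split(sort(names(labels)), labels[sort(names(labels))])
  small <- vapply(classes, length, 1L) < k
  if (any(small)) {
    stop("cannot build ", k, "-fold stratified partition: class '",
         names(classes)[small][1], "' has fewer than ", k, " samples")
  }
  fold <- integer(length(labels))
  names(fold) <- sort(names(labels))
  with_seed(seed, {
    for (ids in classes) {
      ids <- sample(ids)
      fold[ids] <- rep_len(seq_len(k), length(ids))
    }
  })
  fold
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of the ROC curve over all score thresholds.
#' Tied scores contribute diagonal segments, so the value equals the
#' Mann-Whitney pair-ordering statistic with half credit for ties.
#'
#' @param scores Numeric scores, larger = more likely positive.
#' @param labels Named or unnamed vector with values `"resistant"`
#'   (positive) and `"sensitive"`, aligned with `scores`; or a logical
#'   vector of positives.
#' @return AUC in `[0, 1]`, or `NA` if either class is absent.
#' @export
roc_auc <- function(scores, labels) {
  pos <- as_positive(labels)
  if (length(scores) != length(pos)) stop("scores and labels lengths differ")
  P <- sum(pos); N <- sum(!pos)
  if (P == 0 || N == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- pos[ord]
  # cumulative TP/FP at each distinct threshold (descending)
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[keep] / P
  fp <- cumsum(!y)[keep] / N
  tp <- c(0, tp); fp <- c(0, fp)
  sum(diff(fp) * (tp[-1] + tp[-length(tp)]) / 2)
}

#' Area under the precision-recall curve
#'
#' Trapezoidal integration of precision against recall over all score
#' thresholds, anchored at recall 0 with the precision of the highest
#' threshold.
#'
#' @inheritParams roc_auc
#' @return PR AUC in `[0, 1]`, or `NA` if no positives.
#' @export
pr_auc <- function(scores, labels) {
  pos <- as_positive(labels)
  P <- sum(pos)
  if (P == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- pos[ord]
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[keep]
  n_pred <- seq_along(s)[keep]
  rec <- tp / P
  prec <- tp / n_pred
  rec <- c(0, rec); prec <- c(prec[1], prec)
  sum(diff(rec) * (prec[-1] + prec[-length(prec)]) / 2)
}

as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  uu <- unique(labels)
  bad <- setdiff(uu, c(.positive_class, .negative_class))
  if (length(bad) > 0) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  labels == .positive_class
}

#' Confusion-matrix metrics at a probability cutoff
#'
#' Counts the 2x2 confusion matrix with `"resistant"` as the positive class
#' (predicted positive when `score > cutoff`) and derives the usual ratio
#' metrics. Ratios with a zero denominator are reported as `NA`, never 0.
#'
#' @inheritParams roc_auc
#' @param cutoff Probability cutoff in (0, 1).
#' @return List with counts `tp`, `fp`, `tn`, `fn` and metrics `accuracy`,
#'   `recall`, `precision`, `npv`, `specificity`, `f1`.
#' @export
confusion_metrics <- function(scores, labels, cutoff = 0.5) {
  pos <- as_positive(labels)
  pred <- scores > cutoff
  tp <- sum(pred & pos); fp <- sum(pred & !pos)
  tn <- sum(!pred & !pos); fn <- sum(!pred & pos)
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  prec <- rat(tp, tp + fp)
  rec <- rat(tp, tp + fn)
  f1 <- if (is.na(prec) || is.na(rec) || (prec + rec) == 0) NA_real_ else
    2 * prec * rec / (prec + rec)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = rat(tp + tn, tp + fp + tn + fn),
       recall = rec, precision = prec,
       npv = rat(tn, tn + fn),
       specificity = rat(tn, tn + fp),
       f1 = f1)
}

#' L2-regularized logistic regression (Newton solver)
#'
#' Minimizes `sum(log-loss) + ||w||^2 / (2C)` with an unpenalized
#' intercept, the objective used by the elimination and signature stages.
#' Inputs are expected already standardized; the solver itself does not
#' rescale.
#'
#' @param x Numeric matrix, samples in rows.
#' @param y 0/1 response (1 = positive class).
#' @param C Inverse regularization strength (> 0).
#' @param max_iter Newton iteration cap.
#' @param tol Convergence tolerance on the gradient max-norm.
#' @return List with `coefficients` (named), `intercept`, `converged`,
#'   `iterations`.
#' @keywords internal
ridge_logistic <- function(x, y, C = 1.0, max_iter = 1000L, tol = 1e-10) {
  stopifnot(is.matrix(x), nrow(x) == length(y), C > 0)
  n <- nrow(x); p <- ncol(x)
  X <- cbind(`(Intercept)` = 1, x)
  pen <- c(0, rep(1 / C, p))
  beta <- numeric(p + 1L)
  obj <- function(b) {
    eta <- drop(X %*% b)
    # log(1 + exp(eta)) - y*eta, computed stably
    sum(pmax(eta, 0) + log1p(exp(-abs(eta))) - y * eta) + sum(pen * b^2) / 2
  }
  f_old <- obj(beta)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    g <- drop(crossprod(X, mu - y)) + pen * beta
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X * w, X) + diag(pen, p + 1L)
    step <- solve(H, g)
    # backtracking line search on the penalized deviance
    t_step <- 1
    repeat {
      beta_new <- beta - t_step * step
      f_new <- obj(beta_new)
      if (f_new <= f_old + 1e-12 || t_step < 1e-8) break
      t_step <- t_step / 2
    }
    if (abs(f_old - f_new) < tol * (abs(f_old) + 1)) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
    f_old <- f_new
  }
  coefs <- beta[-1L]
  names(coefs) <- colnames(x)
  list(coefficients = coefs, intercept = unname(beta[1L]),
       converged = converged, iterations = it)
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b Vectors of cluster/class labels over the same elements.
#' @return ARI in `[-1, 1]`; 1 for identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
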