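# Candidate-panel construction and pruning: sign-partitioned
# intersection of the DEG and SHAP gene sets, then recursive elimination
# of the gene with the smallest absolute standardized logistic
# coefficient, scoring every panel size by cross-validated specificity.

#' Sign-partitioned intersection of DEG and SHAP gene sets
#'
#' @param deg_up,deg_down Disjoint character vectors of up- and
#'   down-regulated DEGs (resistant over sensitive).
#' @param shap_genes Character vector of SHAP-contributing genes.
#' @return List of class `candidate_panel`: `up`, `down`, `genes`
#'   (sorted union).
#' @export
sign_intersection <- function(deg_up, deg_down, shap_genes) {
  if (length(intersect(deg_up, deg_down)) > 0) {
    stop("deg_up and deg_down must be disjoint")
  }
  up <- sort(intersect(deg_up, shap_genes))
  down <- sort(intersect(deg_down, shap_genes))
  structure(list(up = up, down = down, genes = sort(c(up, down))),
            class = "candidate_panel")
}

#' @export
print.candidate_panel <- function(x, ...) {
  cat("Candidate panel:", length(x$up), "up +", length(x$down),
      "down =", length(x$genes), "genes\n")
  invisible(x)
}

#' Standardized L2-logistic coefficients
#'
#' Centers and scales each feature to unit variance on the fitting data,
#' then fits an L2-penalized logistic regression (inverse regularization
#' `C`, unpenalized intercept) and returns the coefficients on the
#' standardized scale. Zero-variance features get coefficient 0 with a
#' warning.
#'
#' @param features Gene x sample numeric matrix.
#' @param labels Named character class vector (`"resistant"` coded 1).
#' @param C Inverse regularization strength (default 1.0).
#' @param max_iter Iteration cap (default 1000).
#' @return Named numeric vector of standardized coefficients, with the
#'   intercept as attribute `"intercept"`.
#' @export
standardized_logit_coefficients <- function(features, labels, C = 1.0,
                                            max_iter = 1000L) {
  check_binary_labels(labels)
  ids <- colnames(features)
  lab <- labels[ids]
  if (sum(lab == .positive_class) < 2 || sum(lab == .negative_class) < 2) {
    stop("each class needs >= 2 samples")
  }
  X <- t(features)
  if (any(!is.finite(X))) stop("features must be finite")
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  zero_var <- scl == 0
  if (any(zero_var)) {
    warning("zero-variance feature(s): ",
            paste(colnames(X)[zero_var], collapse = ", "),
            "; coefficient set to 0")
  }
  coefs <- setNames(numeric(ncol(X)), colnames(X))
  Xs <- scale(X[, !zero_var, drop = FALSE], center = ctr[!zero_var],
              scale = scl[!zero_var])
  fit <- ridge_logistic(Xs, as.integer(lab == .positive_class), C = C,
                        max_iter = max_iter)
  coefs[!zero_var] <- fit$coefficients
  attr(coefs, "intercept") <- fit$intercept
  coefs
}

# Cross-validated specificity of an L2-logistic model on a gene panel.
# Standardization is refitted inside every training fold; prediction at
# probability cutoff 0.5; specificity = true sensitive predicted
# sensitive / all true sensitive.
cv_specificity <- function(features, lab, fold, C = 1.0) {
  k <- max(fold)
  spec <- numeric(k)
  for (f in seq_len(k)) {
    tr <- names(fold)[fold != f]
    te <- names(fold)[fold == f]
    Xtr <- t(features[, tr, drop = FALSE])
    Xte <- t(features[, te, drop = FALSE])
    ctr <- colMeans(Xtr)
    scl <- apply(Xtr, 2, sd)
    scl[scl == 0] <- 1
    fit <- ridge_logistic(scale(Xtr, ctr, scl),
                          as.integer(lab[tr] == .positive_class), C = C)
    eta <- drop(scale(Xte, ctr, scl) %*% fit$coefficients) + fit$intercept
    pred_res <- 1 / (1 + exp(-eta)) > 0.5
    truth_sen <- lab[te] == .negative_class
    spec[f] <- if (sum(truth_sen) == 0) NA_real_ else
      sum(!pred_res & truth_sen) / sum(truth_sen)
  }
  spec
}

#' Recursive specificity-scored elimination
#'
#' Starting from the full candidate panel, repeatedly (1) scores the
#' current panel's specificity by stratified `n_folds`-fold
#' cross-validation (standardization refitted per training fold,
#' prediction at cutoff 0.5), (2) fits the standardized L2-logistic model
#' on all samples and (3) drops the gene with the smallest absolute
#' standardized coefficient (ties broken toward the lexicographically
#' smallest gene id), until one gene remains. The fold partition is drawn
#' once and reused across panel sizes so the specificity curve is
#' comparable.
#'
#' @param features Gene x sample matrix restricted to the candidate
#'   panel.
#' @param labels Named character class vector.
#' @param n_folds CV folds (default 5).
#' @param seed Seed for the fold partition.
#' @param C Inverse regularization strength (default 1.0).
#' @return Object of class `elimination_trace`: `trace` (data frame
#'   `panel_size`, `mean_specificity`, `sd_specificity`,
#'   `eliminated_gene`), `panels` (list mapping panel size to gene set),
#'   `elimination_order`.
#' @export
recursive_specificity_elimination <- function(features, labels, n_folds = 5,
                                              seed = 1, C = 1.0) {
  check_binary_labels(labels)
  if (nrow(features) < 1) stop("candidate panel is empty")
  ids <- colnames(features)
  lab <- labels[ids]
  fold <- stratified_folds(lab, n_folds, seed)
  fold <- fold[ids[order(ids)]]
  panel <- sort(rownames(features))
  trace <- data.frame(panel_size = integer(0), mean_specificity = numeric(0),
                      sd_specificity = numeric(0),
                      eliminated_gene = character(0))
  panels <- list()
  order_out <- character(0)
  while (length(panel) >= 1) {
    sub <- features[panel, , drop = FALSE]
    spec <- cv_specificity(sub, lab, fold, C = C)
    panels[[as.character(length(panel))]] <- panel
    if (length(panel) > 1) {
      coefs <- suppressWarnings(
        standardized_logit_coefficients(sub, lab, C = C))
      # smallest |coefficient|; ties toward the smallest gene id
      ord <- order(abs(coefs), names(coefs))
      drop_gene <- names(coefs)[ord[1]]
    } else {
      drop_gene <- NA_character_
    }
    trace <- rbind(trace, data.frame(
      panel_size = length(panel),
      mean_specificity = mean(spec, na.rm = TRUE),
      sd_specificity = sd(spec, na.rm = TRUE),
      eliminated_gene = drop_gene))
    if (length(panel) == 1) break
    order_out <- c(order_out, drop_gene)
    panel <- setdiff(panel, drop_gene)
  }
  structure(list(trace = trace, panels = panels,
                 elimination_order = order_out, n_folds = n_folds,
                 seed = seed, C = C),
            class = "elimination_trace")
}

#' @export
print.elimination_trace <- function(x, ...) {
  best <- optimal_panel(x)
  cat("Recursive elimination over", max(x$trace$panel_size), "genes;",
      "peak mean specificity",
      sprintf("%.3f", max(x$trace$mean_specificity)),
      "at panel size", length(best), "\n")
  invisible(x)
}

#' Panel size with maximal cross-validated specificity
#'
#' Ties in mean specificity are broken toward the larger panel: when
#' cross-validation cannot distinguish panel sizes, every retained gene
#' still carries independent differential-expression and attribution
#' evidence, and keeping the redundancy hedges estimation noise at no
#' cost to the fixed assay.
#'
#' @param trace An `elimination_trace`.
#' @return Character vector: the gene set at the panel size with maximum
#'   mean specificity (ties broken toward the larger panel).
#' @export
optimal_panel <- function(trace) {
  stopifnot(inherits(trace, "elimination_trace"))
  tr <- trace$trace
  best <- max(tr$mean_specificity)
  sizes <- tr$panel_size[tr$mean_specificity == best]
  trace$panels[[as.character(max(sizes))]]
}

#' Pairwise Pearson correlations within a panel
#'
#' @param features Gene x sample matrix restricted to the panel
#'   (>= 2 genes).
#' @return List: `matrix` (gene x gene Pearson correlation, unit
#'   diagonal; `NA` for zero-variance genes), `max_abs_offdiag`.
#' @export
panel_correlation <- function(features) {
  if (nrow(features) < 2) stop("need >= 2 genes")
  zero_var <- apply(features, 1, sd) == 0
  m <- suppressWarnings(cor(t(features)))
  m[zero_var, ] <- NA_real_
  m[, zero_var] <- NA_real_
  diag(m) <- ifelse(zero_var, NA_real_, 1)
  off <- abs(m[upper.tri(m)])
  list(matrix = m,
       max_abs_offdiag = if (all(is.na(off))) NA_real_ else max(off, na.rm = TRUE))
}
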