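# The final signature predictor: an L2-regularized logistic model on the
# optimal gene panel, fitted on standardized log-TPM features. The fitted
# object carries its own standardization so any sample with the panel
# genes can be scored; scores are resistant-class probabilities.

#' Fit the logistic signature model
#'
#' Standardizes each panel gene on the training samples, fits an
#' L2-penalized logistic regression (inverse regularization `C`,
#' unpenalized intercept, Newton solver with an iteration cap) and
#' returns a self-contained scorer.
#'
#' @param features Gene x sample matrix restricted to the signature
#'   panel.
#' @param labels Named character class vector covering the samples; both
#'   classes must be present.
#' @param C Inverse regularization strength (default 1.0).
#' @param iteration_cap Newton iteration cap (default 1000).
#' @param cutoff Default operating probability cutoff (default 0.5).
#' @return Object of class `signature_model` with elements `genes`,
#'   `coefficients` (standardized scale), `intercept`, `center`, `scale`,
#'   `positive_class`, `cutoff`, `converged`, `C`, `iteration_cap`.
#' @export
fit_signature <- function(features, labels, C = 1.0, iteration_cap = 1000L,
                          cutoff = 0.5) {
  check_binary_labels(labels)
  ids <- colnames(features)
  lab <- labels[ids]
  if (length(unique(lab)) < 2) stop("both classes must be present")
  X <- t(features)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  if (any(scl == 0)) {
    warning("zero-variance panel gene(s): ",
            paste(colnames(X)[scl == 0], collapse = ", "))
  }
  scl_use <- ifelse(scl == 0, 1, scl)
  fit <- ridge_logistic(scale(X, ctr, scl_use),
                        as.integer(lab == .positive_class),
                        C = C, max_iter = iteration_cap)
  structure(list(genes = rownames(features),
                 coefficients = fit$coefficients,
                 intercept = fit$intercept,
                 center = ctr, scale = scl_use,
                 positive_class = .positive_class,
                 cutoff = cutoff, C = C,
                 iteration_cap = as.integer(iteration_cap),
                 converged = fit$converged,
                 n_train = nrow(X)),
            class = "signature_model")
}

#' Score samples with a signature model
#'
#' @param object A `signature_model`.
#' @param newdata Gene x sample matrix containing every panel gene (extra
#'   genes ignored), or a named numeric vector for one sample.
#' @param type `"score"` for resistant-class probabilities, `"class"` for
#'   labels at the cutoff.
#' @param cutoff Probability cutoff (defaults to the model's).
#' @param ... Unused.
#' @return Named numeric scores in `[0, 1]`, or class labels.
#' @export
predict.signature_model <- function(object, newdata,
                                    type = c("score", "class"),
                                    cutoff = NULL, ...) {
  type <- match.arg(type)
  if (is.null(cutoff)) cutoff <- object$cutoff
  if (is.null(dim(newdata))) newdata <- matrix(newdata, ncol = 1,
                                               dimnames = list(names(newdata),
                                                               "sample"))
  miss <- setdiff(object$genes, rownames(newdata))
  if (length(miss) > 0) {
    stop("missing panel gene(s) in newdata: ", paste(miss, collapse = ", "))
  }
  X <- t(newdata[object$genes, , drop = FALSE])
  Z <- scale(X, object$center, object$scale)
  eta <- drop(Z %*% object$coefficients) + object$intercept
  score <- 1 / (1 + exp(-eta))
  names(score) <- colnames(newdata)
  if (type == "score") return(score)
  setNames(ifelse(score > cutoff, .positive_class, .negative_class),
           names(score))
}

#' Alias for scoring samples with the signature
#'
#' @inheritParams predict.signature_model
#' @param model A `signature_model`.
#' @return Named numeric scores in `[0, 1]`.
#' @export
predict_score <- function(model, newdata) {
  predict(model, newdata, type = "score")
}

#' @export
print.signature_model <- function(x, ...) {
  cat("Logistic sensitivity signature over", length(x$genes),
      "genes (C =", x$C, ", cutoff =", x$cutoff, ")\n")
  cat("  positive class:", x$positive_class,
      if (!x$converged) " [did not converge]" else "", "\n")
  invisible(x)
}

#' @export
summary.signature_model <- function(object, ...) {
  df <- data.frame(gene = object$genes,
                   center = unname(object$center),
                   scale = unname(object$scale),
                   coefficient = unname(object$coefficients))
  df <- df[order(-abs(df$coefficient)), ]
  rownames(df) <- NULL
  structure(list(coefficients = df, intercept = object$intercept,
                 cutoff = object$cutoff, C = object$C,
                 n_train = object$n_train),
            class = "summary.signature_model")
}

#' @export
print.summary.signature_model <- function(x, ...) {
  cat("Signature model fitted on", x$n_train, "samples; intercept",
      sprintf("%.4f", x$intercept), "\n")
  print(head(x$coefficients, 10))
  if (nrow(x$coefficients) > 10) cat("  ...", nrow(x$coefficients) - 10,
                                     "more genes\n")
  invisible(x)
}

#' @export
coef.signature_model <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' Plot signature coefficients
#'
#' Horizontal barplot of standardized coefficients, ordered by absolute
#' value; positive coefficients push samples toward the resistant call.
#'
#' @param x A `signature_model`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.signature_model <- function(x, ...) {
  co <- sort(x$coefficients, decreasing = FALSE)
  graphics::barplot(co, horiz = TRUE, las = 1,
                    xlab = "standardized logistic coefficient",
                    main = "Signature coefficients", ...)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' Classification metrics across probability cutoffs
#'
#' Sweeps the decision cutoff and reports confusion-matrix metrics at
#' each value, with resistant as the positive class. Ratios with zero
#' denominator (e.g. precision when nothing is called resistant) are
#' `NA`, never 0.
#'
#' @param scores Numeric signature scores.
#' @param labels Character class vector aligned with `scores`.
#' @param cutoffs Cutoffs to evaluate (default 0.1 to 0.9 by 0.1).
#' @return Data frame: `cutoff`, `accuracy`, `recall`, `precision`,
#'   `npv`, `specificity`, `f1`, `tp`, `fp`, `tn`, `fn`.
#' @export
cutoff_sweep <- function(scores, labels,
                         cutoffs = seq(0.1, 0.9, by = 0.1)) {
  rows <- lapply(cutoffs, function(cut) {
    cm <- confusion_metrics(scores, labels, cutoff = cut)
    data.frame(cutoff = cut, accuracy = cm$accuracy, recall = cm$recall,
               precision = cm$precision, npv = cm$npv,
               specificity = cm$specificity, f1 = cm$f1,
               tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn)
  })
  do.call(rbind, rows)
}

#' Holdout metrics for a signature model
#'
#' @inheritParams evaluate_holdout
#' @param model A `signature_model`.
#' @return A `holdout_metrics` object (see [evaluate_holdout()]).
#' @export
evaluate_signature <- function(model, features, labels) {
  evaluate_holdout(model, features, labels)
}

#' Write a signature model as a plain-text descriptor
#'
#' Emits a rescorable description: per-gene center, scale and
#' coefficient, plus intercept and cutoff lines, so any implementation
#' can reproduce the scores.
#'
#' @param model A `signature_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_signature <- function(model, path) {
  stopifnot(inherits(model, "signature_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# intercept\t%.17g", model$intercept),
               sprintf("# cutoff\t%.17g", model$cutoff),
               sprintf("# C\t%.17g", model$C),
               sprintf("# positive_class\t%s", model$positive_class),
               "gene\tcenter\tscale\tcoefficient"), con)
  writeLines(sprintf("%s\t%.17g\t%.17g\t%.17g", model$genes,
                     model$center, model$scale, model$coefficients), con)
  invisible(path)
}

#' Read a signature model descriptor
#'
#' @param path Path written by [write_signature()].
#' @return A `signature_model`.
#' @export
read_signature <- function(path) {
  lines <- readLines(path)
  hdr <- lines[grepl("^#", lines)]
  get_val <- function(key) {
    strsplit(hdr[grepl(paste0("^# ", key, "\t"), hdr)], "\t")[[1]][2]
  }
  body <- read.delim(text = lines[!grepl("^#", lines)], sep = "\t")
  structure(list(genes = body$gene,
                 coefficients = setNames(body$coefficient, body$gene),
                 intercept = as.numeric(get_val("intercept")),
                 center = setNames(body$center, body$gene),
                 scale = setNames(body$scale, body$gene),
                 positive_class = get_val("positive_class"),
                 cutoff = as.numeric(get_val("cutoff")),
                 C = as.numeric(get_val("C")),
                 iteration_cap = NA_integer_, converged = NA,
                 n_train = NA_integer_),
            class = "signature_model")
}
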