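# External-validity statistics for a fitted signature: Kaplan-Meier /
# log-rank / Cox survival stratification, landmark ROC at fixed horizons,
# fold-change concordance, and the cross-drug IC50 fold-change panel with
# Welch tests. Survival machinery is delegated to the survival package;
# the wrappers fix the conventions (Breslow ties, Wald CIs, exclusion
# rules) and the reporting format.

#' Kaplan-Meier estimate
#'
#' Product-limit survival estimate with the median defined as the
#' earliest time at which the curve drops to 0.5 or below (`NA` if it
#' never does).
#'
#' @param times Positive follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @return List: `curve` (data frame `time`, `n_risk`, `n_event`,
#'   `surv`), `median`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stop("empty survival table")
  if (any(times <= 0)) stop("times must be positive")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  curve <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, surv = fit$surv)
  med <- if (any(fit$surv <= 0.5)) min(fit$time[fit$surv <= 0.5]) else NA_real_
  list(curve = curve, median = med)
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic with hypergeometric variance at each
#' distinct event time; p from chi-square with 1 df.
#'
#' @param time_a,event_a Times and event flags for group A.
#' @param time_b,event_b Times and event flags for group B.
#' @return List: `chisq`, `p` (both `NA` with a `reason` if there are no
#'   events).
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (length(time_a) == 0 || length(time_b) == 0) {
    stop("both groups must be non-empty")
  }
  if (sum(event_a) + sum(event_b) == 0) {
    return(list(chisq = NA_real_, p = NA_real_, reason = "no events"))
  }
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(c("A", "B"), c(length(time_a), length(time_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, rho = 0)
  list(chisq = sd$chisq,
       p = pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional hazards fit with estimability guards
#'
#' Fits a Cox model (Breslow tie handling) for the listed covariates and
#' reports hazard ratios with Wald 95% CIs. Covariates observed at a
#' single level (or with zero variance) are excluded from the fit and
#' reported with `estimable = FALSE` rather than fabricated.
#'
#' @param data Data frame with columns `time`, `event` and the
#'   covariates.
#' @param covariates Character vector of covariate column names.
#' @return Data frame of class `cox_result`: `term`, `hazard_ratio`,
#'   `ci_low`, `ci_high`, `p`, `estimable`.
#' @export
cox_fit <- function(data, covariates) {
  stopifnot(all(c("time", "event") %in% names(data)),
            all(covariates %in% names(data)))
  if (sum(data$event) < 1) stop("need at least one event")
  est <- vapply(covariates, function(v) {
    x <- data[[v]][!is.na(data[[v]])]
    if (is.numeric(x)) length(unique(x)) >= 2 else length(unique(x)) >= 2
  }, logical(1))
  out <- list()
  if (any(est)) {
    fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                   paste(covariates[est], collapse = " + ")))
    fit <- survival::coxph(fml, data = data, ties = "breslow")
    if (!is.null(fit$info) && any(grepl("did not converge", fit$info))) {
      stop("Cox partial-likelihood maximization did not converge")
    }
    s <- summary(fit)
    co <- s$coefficients
    ci <- s$conf.int
    out[[1]] <- data.frame(term = rownames(co),
                           hazard_ratio = co[, "exp(coef)"],
                           ci_low = ci[, "lower .95"],
                           ci_high = ci[, "upper .95"],
                           p = co[, "Pr(>|z|)"],
                           estimable = TRUE, row.names = NULL)
  }
  if (any(!est)) {
    out[[2]] <- data.frame(term = covariates[!est],
                           hazard_ratio = NA_real_, ci_low = NA_real_,
                           ci_high = NA_real_, p = NA_real_,
                           estimable = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("cox_result", "data.frame")
  res
}

#' Landmark ROC AUC at a fixed horizon
#'
#' Positives are patients with an observed event by the horizon;
#' negatives are patients followed event-free beyond it; patients
#' censored before the horizon are excluded from both classes.
#'
#' @param scores Numeric risk scores (higher = more at risk).
#' @param times Follow-up times.
#' @param events Event flags.
#' @param horizon Positive landmark time (same units as `times`).
#' @return List: `auc` (`NA` with `reason` if a class is empty),
#'   `n_pos`, `n_neg`, `n_excluded`.
#' @export
landmark_roc <- function(scores, times, events, horizon) {
  if (horizon <= 0) stop("horizon must be positive")
  pos <- events == 1 & times <= horizon
  neg <- times > horizon
  excl <- events == 0 & times <= horizon
  if (sum(pos) == 0 || sum(neg) == 0) {
    return(list(auc = NA_real_, n_pos = sum(pos), n_neg = sum(neg),
                n_excluded = sum(excl),
                reason = "empty positive or negative set at this horizon"))
  }
  keep <- pos | neg
  auc <- roc_auc(scores[keep], pos[keep])
  list(auc = auc, n_pos = sum(pos), n_neg = sum(neg),
       n_excluded = sum(excl))
}

#' Welch two-sample t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and two-sided p. When both arms have zero variance and equal
#' means the test degenerates to `t = 0, p = 1` rather than erroring.
#'
#' @param x,y Numeric vectors, each with >= 2 values.
#' @return List: `t`, `df`, `p`.
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("each arm needs >= 2 values")
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    }
    return(list(t = Inf * sign(mean(x) - mean(y)),
                df = length(x) + length(y) - 2, p = 0))
  }
  tt <- t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Cross-drug IC50 fold-change panel
#'
#' For each drug, compares natural-log IC50 between predicted resistant
#' and sensitive lines with a Welch test; the fold change is the
#' exponentiated difference of arm means (geometric-mean ratio
#' resistant/sensitive) with a 95% CI built on the log scale using the
#' Welch degrees of freedom, then exponentiated. Drugs with fewer than 2
#' values per arm are skipped with a reason.
#'
#' @param panel Cell line x drug IC50 matrix (rownames = line ids);
#'   missing values allowed.
#' @param labels Named character class vector of predicted labels.
#' @param bh_correct Apply BH correction across drugs (default `FALSE`).
#' @return Data frame: `drug`, `n_sensitive`, `n_resistant`,
#'   `fold_change`, `ci_low`, `ci_high`, `p` (and `padj` if corrected),
#'   `skipped`, `reason`.
#' @export
drug_panel_compare <- function(panel, labels, bh_correct = FALSE) {
  check_binary_labels(labels)
  ids <- intersect(rownames(panel), names(labels))
  rows <- lapply(colnames(panel), function(drug) {
    v <- panel[ids, drug]
    ok <- !is.na(v) & v > 0
    res <- v[ok & labels[ids] == .positive_class]
    sen <- v[ok & labels[ids] == .negative_class]
    base <- data.frame(drug = drug, n_sensitive = length(sen),
                       n_resistant = length(res))
    if (length(res) < 2 || length(sen) < 2) {
      return(cbind(base, fold_change = NA_real_, ci_low = NA_real_,
                   ci_high = NA_real_, p = NA_real_, skipped = TRUE,
                   reason = "fewer than 2 lines in an arm"))
    }
    lx <- log(res); ly <- log(sen)
    wt <- welch_t_test(lx, ly)
    diff <- mean(lx) - mean(ly)
    se <- sqrt(var(lx) / length(lx) + var(ly) / length(ly))
    half <- if (se == 0) 0 else qt(0.975, wt$df) * se
    cbind(base, fold_change = exp(diff), ci_low = exp(diff - half),
          ci_high = exp(diff + half), p = wt$p, skipped = FALSE,
          reason = NA_character_)
  })
  out <- do.call(rbind, rows)
  if (bh_correct) {
    out$padj <- NA_real_
    ok <- !out$skipped
    out$padj[ok] <- bh_adjust(out$p[ok])
  }
  out
}

#' Pearson concordance of two fold-change vectors
#'
#' @param log2fc_a,log2fc_b Paired numeric vectors (length >= 3), e.g.
#'   training-data log2 fold changes against an external measurement.
#' @return List: `r`, `p` (two-sided, from the t transform); `NA` with a
#'   `reason` when a vector has zero variance.
#' @export
foldchange_concordance <- function(log2fc_a, log2fc_b) {
  if (length(log2fc_a) != length(log2fc_b)) stop("vectors must be paired")
  if (length(log2fc_a) < 3) stop("need at least 3 pairs")
  if (sd(log2fc_a) == 0 || sd(log2fc_b) == 0) {
    return(list(r = NA_real_, p = NA_real_,
                reason = "zero variance in a vector"))
  }
  ct <- cor.test(log2fc_a, log2fc_b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
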