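# Differential expression between resistant and sensitive groups: a
# deliberately small negative-binomial Wald test with median-of-ratios
# normalization, method-of-moments dispersion and BH correction. The aim
# is a transparent, fully specified DEG gate (padj < 0.05, |log2FC| > 1),
# not a reimplementation of a full shrinkage estimator.

#' Median-of-ratios size factors
#'
#' For each sample, the median across reference genes (genes with
#' positive counts in every sample) of the ratio of its count to the
#' gene's geometric mean, normalized so the factors have geometric
#' mean 1.
#'
#' @param counts Nonnegative gene x sample count matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) {
    stop("no gene has positive counts in every sample; ",
         "relax low-expression filtering before computing size factors")
  }
  logc <- log(counts[ref, , drop = FALSE])
  loggeo <- rowMeans(logc)
  sf <- exp(apply(logc - loggeo, 2, median))
  sf / exp(mean(log(sf)))
}

#' Negative-binomial Wald test per gene
#'
#' For each gene, compares normalized group means between resistant and
#' sensitive samples. The dispersion is a pooled method-of-moments
#' estimate on normalized counts floored at 1e-8; the log2 fold change
#' (resistant over sensitive) uses a pseudo-count of 0.5 when a group
#' mean is zero; the standard error comes from the delta method on the
#' NB variance; p is two-sided normal. All-zero genes return
#' `log2fc = 0, p = 1`.
#'
#' @param counts Gene x sample count matrix.
#' @param sf Size factors from [size_factors()].
#' @param labels Named character vector (`"resistant"`/`"sensitive"`)
#'   covering the columns of `counts`; each group needs >= 2 samples.
#' @return Data frame: `gene`, `log2fc`, `se`, `p`.
#' @export
nb_wald <- function(counts, sf, labels) {
  check_binary_labels(labels)
  ids <- colnames(counts)
  if (!all(ids %in% names(labels))) stop("labels must cover all samples")
  lab <- labels[ids]
  res <- lab == .positive_class
  sen <- lab == .negative_class
  if (sum(res) < 2 || sum(sen) < 2) stop("each group needs >= 2 samples")
  sfv <- sf[ids]
  q <- sweep(as.matrix(counts), 2, sfv, "/")

  n1 <- sum(res); n0 <- sum(sen)
  m1 <- rowMeans(q[, res, drop = FALSE])
  m0 <- rowMeans(q[, sen, drop = FALSE])
  v1 <- apply(q[, res, drop = FALSE], 1, var)
  v0 <- apply(q[, sen, drop = FALSE], 1, var)
  s2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
  mu <- (n1 * m1 + n0 * m0) / (n1 + n0)
  alpha <- ifelse(mu > 0, pmax((s2 - mu) / mu^2, 1e-8), 1e-8)

  m1p <- ifelse(m1 == 0, 0.5, m1)
  m0p <- ifelse(m0 == 0, 0.5, m0)
  log2fc <- log2(m1p / m0p)

  # Var of a normalized group mean under NB(mu*sf, alpha):
  # (1/n^2) * sum_j (m/sf_j + alpha m^2)
  inv_sf1 <- sum(1 / sfv[res]); inv_sf0 <- sum(1 / sfv[sen])
  V1 <- (m1p * inv_sf1 + alpha * m1p^2 * n1) / n1^2
  V0 <- (m0p * inv_sf0 + alpha * m0p^2 * n0) / n0^2
  se <- sqrt(V1 / m1p^2 + V0 / m0p^2) / log(2)
  z <- log2fc / se
  p <- 2 * pnorm(-abs(z))

  allzero <- m1 == 0 & m0 == 0
  log2fc[allzero] <- 0
  p[allzero] <- 1
  se[allzero] <- NA_real_

  data.frame(gene = rownames(counts), log2fc = log2fc, se = se, p = p,
             row.names = NULL)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement, capped at 1,
#' returned in the original order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must be finite and in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' Strict thresholds: up = `padj < padj_threshold` and
#' `log2fc > lfc_threshold`; down likewise with `log2fc <
#' -lfc_threshold`.
#'
#' @param records Data frame with columns `gene`, `log2fc`, `padj`.
#' @param padj_threshold Adjusted-p gate (default 0.05).
#' @param lfc_threshold Absolute log2 fold-change gate (default 1).
#' @return List with character vectors `up` and `down`.
#' @export
call_deg <- function(records, padj_threshold = 0.05, lfc_threshold = 1) {
  stopifnot(all(c("gene", "log2fc", "padj") %in% names(records)))
  sig <- records$padj < padj_threshold
  list(up = records$gene[sig & records$log2fc > lfc_threshold],
       down = records$gene[sig & records$log2fc < -lfc_threshold])
}

#' Full differential-expression stage
#'
#' Convenience wrapper: size factors, NB Wald test, BH adjustment and
#' significance calls in one step.
#'
#' @inheritParams nb_wald
#' @inheritParams call_deg
#' @return List of class `deg_result`: `records` (with `padj` and `call`
#'   columns added), `up`, `down`, `size_factors`.
#' @export
run_deg <- function(counts, labels, padj_threshold = 0.05,
                    lfc_threshold = 1) {
  sf <- size_factors(counts)
  rec <- nb_wald(counts, sf, labels)
  rec$padj <- bh_adjust(rec$p)
  calls <- call_deg(rec, padj_threshold, lfc_threshold)
  rec$call <- ifelse(rec$gene %in% calls$up, "up",
                     ifelse(rec$gene %in% calls$down, "down", "ns"))
  structure(list(records = rec, up = calls$up, down = calls$down,
                 size_factors = sf,
                 padj_threshold = padj_threshold,
                 lfc_threshold = lfc_threshold),
            class = "deg_result")
}

#' @export
print.deg_result <- function(x, ...) {
  cat("Differential expression:", nrow(x$records), "genes tested;",
      length(x$up), "up,", length(x$down), "down at padj <",
      x$padj_threshold, "and |log2FC| >", x$lfc_threshold, "\n")
  invisible(x)
}
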