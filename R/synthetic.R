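# Synthetic-cohort generator. Produces the data structures the discovery
# pipeline assumes -- two correlated bimodal IC50 sources with discordant
# subgroups, negative-binomial counts with planted sign-split signature
# genes, a TPM matrix derived from the counts, exponential survival and a
# multi-drug IC50 panel -- with the ground truth recorded so every
# downstream stage can be tested for recovery.

#' Synthetic cohort configuration
#'
#' Parameters of the simulated pharmacogenomic cohort. Defaults mirror the
#' scale of a mid-sized two-source cell-line screen: 60 sensitive and 55
#' resistant lines plus 35 lines whose two IC50 sources disagree, 2,000
#' genes of which 30 carry a planted sensitivity signature (15 up- and 15
#' down-regulated in the resistant class).
#'
#' @param n_sensitive,n_resistant,n_discordant Class sizes. Discordant
#'   lines are split between the two off-diagonal IC50 patterns
#'   (sensitive-like in source A / resistant-like in source B, and the
#'   reverse), so the two-source profile forms four clusters.
#' @param n_genes Number of genes.
#' @param n_signature_up,n_signature_down Planted signature genes up- or
#'   down-regulated in the resistant class.
#' @param signature_log2fc Planted effect size (log2 units, > 0).
#' @param nb_dispersion Negative-binomial dispersion alpha in
#'   `var = mu + alpha * mu^2` (> 0).
#' @param libsize_log_sd SD of per-sample log library-size factors.
#' @param ic50_mu_sensitive,ic50_mu_resistant Class means of ln IC50
#'   (ln uM).
#' @param ic50_log_sd Between-line SD of ln IC50 shared by the sources.
#' @param cross_source_noise_sd Independent per-source ln-scale noise.
#' @param discordant_shrink How far (ln units) the discordant lines'
#'   per-source class means sit inward of the concordant extremes, so the
#'   concordant clusters are strictly the most extreme in both sources
#'   (default 0.25).
#' @param missing_rate Fraction of lines missing one source at random
#'   (IC50 A, IC50 B, or expression), in `[0, 1)`.
#' @param seed Integer seed; identical config + seed reproduces the cohort
#'   bit for bit.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_sensitive = 60, n_resistant = 55, n_discordant = 35,
                         n_genes = 2000, n_signature_up = 15,
                         n_signature_down = 15, signature_log2fc = 2,
                         nb_dispersion = 0.8, libsize_log_sd = 0.2,
                         ic50_mu_sensitive = log(8),
                         ic50_mu_resistant = log(60),
                         ic50_log_sd = 0.18, cross_source_noise_sd = 0.12,
                         discordant_shrink = 0.25,
                         missing_rate = 0, seed = 1) {
  cfg <- list(n_sensitive = n_sensitive, n_resistant = n_resistant,
              n_discordant = n_discordant, n_genes = n_genes,
              n_signature_up = n_signature_up,
              n_signature_down = n_signature_down,
              signature_log2fc = signature_log2fc,
              nb_dispersion = nb_dispersion,
              libsize_log_sd = libsize_log_sd,
              ic50_mu_sensitive = ic50_mu_sensitive,
              ic50_mu_resistant = ic50_mu_resistant,
              ic50_log_sd = ic50_log_sd,
              cross_source_noise_sd = cross_source_noise_sd,
              discordant_shrink = discordant_shrink,
              missing_rate = missing_rate, seed = seed)
  counts <- c("n_sensitive", "n_resistant", "n_discordant", "n_genes",
              "n_signature_up", "n_signature_down")
  for (nm in counts) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v != round(v)) {
      stop("'", nm, "' must be a nonnegative integer")
    }
  }
  if (cfg$n_signature_up + cfg$n_signature_down > cfg$n_genes) {
    stop("n_signature_up + n_signature_down exceeds n_genes")
  }
  if (cfg$signature_log2fc <= 0) stop("signature_log2fc must be > 0")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)")
  }
  if ((cfg$n_sensitive == 0 || cfg$n_resistant == 0) &&
      (cfg$n_signature_up + cfg$n_signature_down) > 0) {
    stop("cannot plant signature genes with an empty class")
  }
  structure(cfg, class = "synth_config")
}

#' Simulate a two-source pharmacogenomic cohort
#'
#' Draws per-line IC50 values log-normally for two screening sources that
#' share a latent per-line value (class mean plus shared between-line
#' noise) and differ by independent source noise; discordant lines take
#' opposite class means in the two sources. Counts are negative-binomial
#' around log-normal gene base means scaled by per-sample library factors,
#' with the planted signature genes shifted by `+/- signature_log2fc` in
#' the resistant class. The TPM matrix is derived from the counts by
#' within-sample total scaling (unit gene lengths) and stored as
#' `log10(TPM + 1)`. When `missing_rate > 0`, the affected lines lack one
#' source at random, which exercises merge filtering downstream.
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_cohort` with elements `ic50_a`, `ic50_b`
#'   (data frames `id`, `ic50` in uM), `counts` and `log_tpm`
#'   (gene x sample matrices), `truth_labels` (named character:
#'   `"sensitive"`, `"resistant"`, `"discordant"`), `truth_genes` (data
#'   frame `gene`, `sign` with `+1` up in resistant / `-1` down), and
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  n <- cfg$n_sensitive + cfg$n_resistant + cfg$n_discordant
  if (n < 2) stop("cohort must contain at least 2 lines")
  ids <- sprintf("CL%04d", seq_len(n))
  truth <- rep(c("sensitive", "resistant", "discordant"),
               c(cfg$n_sensitive, cfg$n_resistant, cfg$n_discordant))
  names(truth) <- ids

  with_seed(cfg$seed, {
    # Class means per source; discordant lines split between the two
    # off-diagonal patterns so the 2-D profile has four modes.
    n_d1 <- ceiling(cfg$n_discordant / 2)   # sensitive-like in A, resistant in B
    disc_pattern <- rep(c("AB_sr", "AB_rs"),
                        c(n_d1, cfg$n_discordant - n_d1))
    mu_a <- ifelse(truth == "sensitive", cfg$ic50_mu_sensitive,
                   cfg$ic50_mu_resistant)
    mu_b <- mu_a
    disc <- which(truth == "discordant")
    mu_sen_d <- cfg$ic50_mu_sensitive + cfg$discordant_shrink
    mu_res_d <- cfg$ic50_mu_resistant - cfg$discordant_shrink
    mu_a[disc] <- ifelse(disc_pattern == "AB_sr", mu_sen_d, mu_res_d)
    mu_b[disc] <- ifelse(disc_pattern == "AB_sr", mu_res_d, mu_sen_d)
    shared_a <- rnorm(n, 0, cfg$ic50_log_sd)
    shared_b <- rnorm(n, 0, cfg$ic50_log_sd)
    # discordant lines have independent latent values per source; concordant
    # lines share one latent draw so the sources correlate
    shared_b[truth != "discordant"] <- shared_a[truth != "discordant"]
    ic50_a <- exp(mu_a + shared_a + rnorm(n, 0, cfg$cross_source_noise_sd))
    ic50_b <- exp(mu_b + shared_b + rnorm(n, 0, cfg$cross_source_noise_sd))

    genes <- sprintf("G%04d", seq_len(cfg$n_genes))
    n_sig <- cfg$n_signature_up + cfg$n_signature_down
    sig_sign <- rep(c(1, -1), c(cfg$n_signature_up, cfg$n_signature_down))
    base_mu <- rlnorm(cfg$n_genes, meanlog = 4, sdlog = 1)
    libf <- exp(rnorm(n, 0, cfg$libsize_log_sd))
    # expected count matrix: base mean x class shift x library factor
    shift <- matrix(0, nrow = cfg$n_genes, ncol = n)
    if (n_sig > 0) {
      res_cols <- truth == "resistant"
      shift[seq_len(n_sig), res_cols] <-
        rep(sig_sign * cfg$signature_log2fc, sum(res_cols))
    }
    mu_mat <- base_mu * 2^shift * rep(libf, each = cfg$n_genes)
    counts <- matrix(rnbinom(length(mu_mat), mu = mu_mat,
                             size = 1 / cfg$nb_dispersion),
                     nrow = cfg$n_genes, dimnames = list(genes, ids))

    tpm <- sweep(counts, 2, pmax(colSums(counts), 1), "/") * 1e6
    log_tpm <- log10(tpm + 1)

    ic50_a_df <- data.frame(id = ids, ic50 = ic50_a)
    ic50_b_df <- data.frame(id = ids, ic50 = ic50_b)

    if (cfg$missing_rate > 0) {
      n_miss <- floor(cfg$missing_rate * n)
      if (n_miss > 0) {
        miss_ids <- sample(ids, n_miss)
        miss_src <- sample(c("a", "b", "expr"), n_miss, replace = TRUE)
        drop_a <- miss_ids[miss_src == "a"]
        drop_b <- miss_ids[miss_src == "b"]
        drop_e <- miss_ids[miss_src == "expr"]
        ic50_a_df <- ic50_a_df[!ic50_a_df$id %in% drop_a, , drop = FALSE]
        ic50_b_df <- ic50_b_df[!ic50_b_df$id %in% drop_b, , drop = FALSE]
        keep <- !colnames(counts) %in% drop_e
        counts <- counts[, keep, drop = FALSE]
        log_tpm <- log_tpm[, keep, drop = FALSE]
      }
    }

    truth_genes <- data.frame(gene = genes[seq_len(n_sig)],
                              sign = sig_sign)[seq_len(n_sig), , drop = FALSE]
    structure(list(ic50_a = ic50_a_df, ic50_b = ic50_b_df,
                   counts = counts, log_tpm = log_tpm,
                   truth_labels = truth, truth_genes = truth_genes,
                   config = cfg),
              class = "synth_cohort")
  })
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat("Synthetic pharmacogenomic cohort\n")
  cat("  lines:", length(x$truth_labels),
      sprintf("(%d sensitive, %d resistant, %d discordant)\n",
              sum(x$truth_labels == "sensitive"),
              sum(x$truth_labels == "resistant"),
              sum(x$truth_labels == "discordant")))
  cat("  genes:", nrow(x$counts), "with", nrow(x$truth_genes),
      "planted signature genes\n")
  invisible(x)
}

#' Simulate survival outcomes for labeled samples
#'
#' Exponential event times with hazard `baseline_rate` for the sensitive
#' group and `baseline_rate * hazard_ratio` for the resistant group, and
#' independent exponential censoring whose rate is tuned so the expected
#' censored fraction equals `censor_rate`.
#'
#' @param groups Named character vector mapping sample id to `"sensitive"`
#'   or `"resistant"`.
#' @param hazard_ratio Resistant-vs-sensitive hazard ratio (> 0).
#' @param baseline_rate Sensitive-group event rate (> 0, events per year).
#' @param censor_rate Expected censored fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @return Data frame with `id`, `time` (years), `event` (1 = event
#'   observed), `group`.
#' @export
simulate_survival <- function(groups, hazard_ratio, baseline_rate = 0.2,
                              censor_rate = 0, seed = 1) {
  check_binary_labels(groups)
  if (hazard_ratio <= 0) stop("hazard_ratio must be > 0")
  if (baseline_rate <= 0) stop("baseline_rate must be > 0")
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must be in [0, 1)")
  n <- length(groups)
  rate <- ifelse(groups == .positive_class,
                 baseline_rate * hazard_ratio, baseline_rate)
  with_seed(seed, {
    t_event <- rexp(n, rate)
    if (censor_rate > 0) {
      # For Exp(lambda) events and Exp(c) censoring, P(censored) = c/(c+lambda)
      c_rate <- censor_rate / (1 - censor_rate) * mean(rate)
      t_cens <- rexp(n, c_rate)
    } else {
      t_cens <- rep(Inf, n)
    }
    data.frame(id = names(groups),
               time = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens),
               group = unname(groups))
  })
}

#' Simulate a multi-drug IC50 panel
#'
#' Log-normal IC50 per drug with the resistant-class ln-mean shifted by
#' `log(2) * effect` relative to sensitive, i.e. a geometric-mean fold
#' change of `2^effect`.
#'
#' @param truth_labels Named character vector of class labels; only
#'   `"sensitive"`/`"resistant"` lines receive values.
#' @param drug_effects Named numeric vector: per-drug log2 fold change
#'   (resistant / sensitive).
#' @param noise_sd Between-line SD of ln IC50.
#' @param seed Integer seed.
#' @param mu_base Baseline ln IC50 (ln uM).
#' @return Matrix, cell lines x drugs, of IC50 values in uM.
#' @export
simulate_drug_panel <- function(truth_labels, drug_effects, noise_sd = 0.5,
                                seed = 1, mu_base = log(10)) {
  if (is.null(names(drug_effects)) || any(!is.finite(drug_effects))) {
    stop("drug_effects must be a named vector of finite log2 fold changes")
  }
  keep <- truth_labels %in% c(.positive_class, .negative_class)
  labs <- truth_labels[keep]
  n <- length(labs)
  if (n == 0) stop("no sensitive/resistant lines in truth_labels")
  with_seed(seed, {
    res <- labs == .positive_class
    panel <- vapply(drug_effects, function(eff) {
      exp(mu_base + log(2) * eff * res + rnorm(n, 0, noise_sd))
    }, numeric(n))
    rownames(panel) <- names(labs)
    panel
  })
}

#' Write a synthetic cohort to delimited files
#'
#' Emits the same formats the readers accept: two-column IC50 tables,
#' gene x sample expression matrices with a header of sample ids, and a
#' truth sidecar (`truth_labels.tsv`, `truth_genes.tsv`).
#'
#' @param cohort A `synth_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synth_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ic50_a = file.path(dir, "ic50_a.tsv"),
             ic50_b = file.path(dir, "ic50_b.tsv"),
             counts = file.path(dir, "counts.tsv"),
             log_tpm = file.path(dir, "log_tpm.tsv"),
             truth_labels = file.path(dir, "truth_labels.tsv"),
             truth_genes = file.path(dir, "truth_genes.tsv"))
  write.table(cohort$ic50_a, paths["ic50_a"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$ic50_b, paths["ic50_b"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_matrix(cohort$counts, paths["counts"])
  write_matrix(cohort$log_tpm, paths["log_tpm"])
  write.table(data.frame(id = names(cohort$truth_labels),
                         label = unname(cohort$truth_labels)),
              paths["truth_labels"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$truth_genes, paths["truth_genes"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}
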