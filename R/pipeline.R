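# End-to-end orchestration: one configuration object drives
# merge -> phenotype labels -> train/test split -> differential
# expression -> SHAP ranking -> sign intersection -> recursive
# elimination -> signature fit -> holdout evaluation, with optional
# survival and drug-panel validation, deterministic under the seed, and
# every intermediate artifact written when an output directory is given.

#' Pipeline configuration
#'
#' @param synthetic A [synth_config()] to simulate inputs, or `NULL` when
#'   `manifest` is given. When left at its default, the cohort seed
#'   follows the master `seed`.
#' @param manifest Path to a key-value manifest naming the four input
#'   files (see [read_cohort()]).
#' @param padj_threshold,lfc_threshold DEG gates (defaults 0.05 and 1).
#' @param epsilon Strict SHAP contribution floor (default 0).
#' @param cutoff Operating probability cutoff (default 0.5).
#' @param n_repeats,n_folds Repeated-CV settings for the SHAP stage
#'   (defaults 12 and 5).
#' @param fraction_test Holdout fraction (default 0.2).
#' @param cut_distance Ward dendrogram cut height retained for the fixed
#'   cut (default 8); silhouette-based selection remains primary.
#' @param min_total Low-expression filter threshold (default 10).
#' @param C Inverse regularization for the logistic stages (default 1.0).
#' @param gbdt_params Booster hyperparameter overrides
#'   (see [train_gbdt()]).
#' @param shap_base_seed Base seed of the repeated-CV SHAP stage
#'   (default 42).
#' @param seed Master seed for splitting, folds and k-means restarts.
#' @param outdir Output directory for artifacts, or `NULL` to skip
#'   writing.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synth_config(), manifest = NULL,
                            padj_threshold = 0.05, lfc_threshold = 1,
                            epsilon = 0, cutoff = 0.5, n_repeats = 12,
                            n_folds = 5, fraction_test = 0.2,
                            cut_distance = 8, min_total = 10, C = 1.0,
                            gbdt_params = list(), shap_base_seed = 42,
                            seed = 1, outdir = NULL) {
  stopifnot(padj_threshold > 0, padj_threshold < 1,
            lfc_threshold >= 0, epsilon >= 0,
            cutoff > 0, cutoff < 1,
            n_repeats >= 1, n_folds >= 2,
            fraction_test > 0, fraction_test < 1)
  if (is.null(synthetic) && is.null(manifest)) {
    stop("provide either a synthetic config or a manifest")
  }
  # a default-constructed synthetic cohort follows the master seed
  if (missing(synthetic) && is.null(manifest)) synthetic$seed <- seed
  structure(list(synthetic = synthetic, manifest = manifest,
                 padj_threshold = padj_threshold,
                 lfc_threshold = lfc_threshold, epsilon = epsilon,
                 cutoff = cutoff, n_repeats = n_repeats,
                 n_folds = n_folds, fraction_test = fraction_test,
                 cut_distance = cut_distance, min_total = min_total,
                 C = C, gbdt_params = gbdt_params,
                 shap_base_seed = shap_base_seed,
                 seed = seed, outdir = outdir),
            class = "pipeline_config")
}

#' Run the signature-discovery pipeline
#'
#' Executes every stage on the configured inputs. Discovery (DEG, SHAP
#' ranking, intersection, elimination, signature fit) uses only the
#' training portion of a stratified split; the held-out portion provides
#' the classifier and signature metrics. With an output directory set,
#' writes the labels, DEG table, SHAP summary, candidate panel,
#' elimination trace, final panel, model descriptor, metrics and a run
#' report, and returns their manifest. Identical config and seed
#' reproduce identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `sensig_run`: all stage results plus
#'   `manifest` (named file paths, empty if no `outdir`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline halted at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- data -----------------------------------------------------------
  cohort <- if (is.null(config$manifest)) {
    stage("simulate", simulate_cohort(config$synthetic))
  }
  data <- stage("merge", {
    if (!is.null(config$manifest)) {
      read_cohort(config$manifest)
    } else {
      merge_cohort(cohort$ic50_a, cohort$ic50_b, cohort$counts,
                   cohort$log_tpm)
    }
  })
  data$counts <- stage("filter", {
    filter_low_expression(data$counts, config$min_total)
  })
  data$log_tpm <- data$log_tpm[rownames(data$counts), , drop = FALSE]

  # -- phenotype labels ----------------------------------------------
  points <- cbind(source_a = data$ic50_a, source_b = data$ic50_b)
  rownames(points) <- data$sample_ids
  clustering <- stage("cluster", {
    choose_clustering(points, seed = config$seed)
  })
  labels_obj <- stage("label", {
    assign_sensitivity(clustering$assignment, data$ic50_a, data$ic50_b)
  })
  labels <- labels_obj$labels

  keep <- names(labels)
  counts <- data$counts[, keep, drop = FALSE]
  log_tpm <- data$log_tpm[, keep, drop = FALSE]

  # -- split ----------------------------------------------------------
  split <- stage("split", {
    stratified_split(labels, config$fraction_test, config$seed)
  })

  # -- differential expression (training samples only) ----------------
  deg <- stage("deg", {
    run_deg(counts[, split$train, drop = FALSE], labels,
            config$padj_threshold, config$lfc_threshold)
  })

  # -- SHAP ranking ----------------------------------------------------
  shap <- stage("rank", {
    shap_repeated_cv(log_tpm[, split$train, drop = FALSE],
                     labels, n_repeats = config$n_repeats,
                     n_folds = config$n_folds,
                     base_seed = config$shap_base_seed,
                     params = config$gbdt_params)
  })
  shap_genes <- contributing_genes(shap, config$epsilon)
  classifier <- stage("rank", {
    train_gbdt(log_tpm[, split$train, drop = FALSE], labels,
               params = config$gbdt_params, seed = config$seed)
  })
  classifier_metrics <- stage("rank", {
    evaluate_holdout(classifier, log_tpm[, split$test, drop = FALSE],
                     labels)
  })

  # -- candidate panel and elimination --------------------------------
  candidate <- stage("select", {
    cp <- sign_intersection(deg$up, deg$down, shap_genes)
    if (length(cp$genes) == 0) {
      stop("empty candidate panel: no overlap between DEG calls (",
           length(deg$up), " up, ", length(deg$down),
           " down) and ", length(shap_genes), " SHAP-contributing genes")
    }
    cp
  })
  trace <- stage("select", {
    recursive_specificity_elimination(
      log_tpm[candidate$genes, split$train, drop = FALSE], labels,
      n_folds = config$n_folds, seed = config$seed, C = config$C)
  })
  panel <- optimal_panel(trace)
  correlation <- if (length(panel) >= 2) {
    panel_correlation(log_tpm[panel, split$train, drop = FALSE])
  } else {
    NULL
  }

  # -- signature fit and evaluation -----------------------------------
  model <- stage("fit", {
    fit_signature(log_tpm[panel, split$train, drop = FALSE], labels,
                  C = config$C, cutoff = config$cutoff)
  })
  signature_metrics <- stage("evaluate", {
    evaluate_signature(model, log_tpm[panel, split$test, drop = FALSE],
                       labels)
  })
  sweep_tab <- cutoff_sweep(signature_metrics$scores,
                            labels[split$test])

  run <- structure(
    list(config = config, cohort = cohort, data = data,
         clustering = clustering, labels = labels_obj, split = split,
         deg = deg, shap = shap, shap_genes = shap_genes,
         classifier = classifier, classifier_metrics = classifier_metrics,
         candidate = candidate, trace = trace, panel = panel,
         correlation = correlation, model = model,
         signature_metrics = signature_metrics, cutoff_sweep = sweep_tab,
         manifest = character(0)),
    class = "sensig_run")

  if (!is.null(config$outdir)) {
    run$manifest <- write_run_artifacts(run, config$outdir)
  }
  run
}

write_run_artifacts <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(labels = "labels.tsv", deg = "deg_table.tsv",
             shap = "shap_summary.tsv", candidate = "candidate_panel.tsv",
             trace = "elimination_trace.tsv", panel = "panel.txt",
             model = "signature_model.tsv", metrics = "metrics.tsv",
             report = "run_report.txt")
  paths <- setNames(file.path(outdir, paths), names(paths))
  write_labels(run$labels, paths["labels"])
  write.table(run$deg$records, paths["deg"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_shap_summary(run$shap, paths["shap"])
  write.table(data.frame(gene = run$candidate$genes,
                         direction = ifelse(run$candidate$genes %in%
                                              run$candidate$up,
                                            "up", "down")),
              paths["candidate"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(run$trace$trace, paths["trace"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(run$panel, paths["panel"])
  write_signature(run$model, paths["model"])
  met <- data.frame(
    stage = c(rep("classifier", 3), rep("signature", 3)),
    metric = rep(c("accuracy", "roc_auc", "pr_auc"), 2),
    value = c(run$classifier_metrics$accuracy,
              run$classifier_metrics$roc_auc,
              run$classifier_metrics$pr_auc,
              run$signature_metrics$accuracy,
              run$signature_metrics$roc_auc,
              run$signature_metrics$pr_auc))
  write.table(met, paths["metrics"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  report <- c(
    "signature discovery run report",
    sprintf("seed: %d", run$config$seed),
    sprintf("samples merged: %d", length(run$data$sample_ids)),
    sprintf("genes after filtering: %d", nrow(run$data$counts)),
    sprintf("clustering: %s, k = %d (mean silhouette %.4f)",
            run$clustering$method, run$clustering$k,
            run$clustering$assignment$silhouette),
    sprintf("labels: %d sensitive, %d resistant, %d excluded",
            sum(run$labels$labels == "sensitive"),
            sum(run$labels$labels == "resistant"),
            length(run$labels$excluded)),
    sprintf("split: %d train / %d test (fraction %.2f)",
            length(run$split$train), length(run$split$test),
            run$config$fraction_test),
    sprintf("DEG: %d up, %d down", length(run$deg$up),
            length(run$deg$down)),
    sprintf("SHAP-contributing genes: %d", length(run$shap_genes)),
    sprintf("candidate panel: %d genes", length(run$candidate$genes)),
    sprintf("final panel: %d genes", length(run$panel)),
    sprintf("signature holdout ROC AUC: %.4f",
            run$signature_metrics$roc_auc))
  writeLines(report, paths["report"])
  paths
}

#' @export
print.sensig_run <- function(x, ...) {
  cat("Sensitivity-signature discovery run (seed", x$config$seed, ")\n")
  cat("  cohort:", length(x$data$sample_ids), "lines;",
      nrow(x$data$counts), "genes after filtering\n")
  cat("  clustering:", x$clustering$method, "k =", x$clustering$k, "\n")
  cat("  labels:", sum(x$labels$labels == "sensitive"), "sensitive /",
      sum(x$labels$labels == "resistant"), "resistant /",
      length(x$labels$excluded), "excluded\n")
  cat("  DEG:", length(x$deg$up), "up,", length(x$deg$down), "down;",
      "SHAP-contributing:", length(x$shap_genes), "\n")
  cat("  candidate panel:", length(x$candidate$genes),
      "-> final panel:", length(x$panel), "genes\n")
  cat(sprintf("  signature holdout: accuracy %.3f, ROC AUC %.3f, PR AUC %.3f\n",
              x$signature_metrics$accuracy, x$signature_metrics$roc_auc,
              x$signature_metrics$pr_auc))
  invisible(x)
}
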