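# Synthetic-cohort generator: structure, determinism, planted effects,
# marginal moments, survival and drug-panel simulators.

test_that("cohort has the configured shape and complete tables", {
  cfg <- synth_config(n_sensitive = 60, n_resistant = 55, n_discordant = 35,
                      n_genes = 200, missing_rate = 0, seed = 3)
  co <- simulate_cohort(cfg)
  expect_equal(length(co$truth_labels), 150)
  expect_equal(nrow(co$ic50_a), 150)
  expect_equal(nrow(co$ic50_b), 150)
  expect_equal(dim(co$counts), c(200, 150))
  expect_equal(dim(co$log_tpm), c(200, 150))
  expect_true(all(colnames(co$counts) %in% names(co$truth_labels)))
  expect_true(all(co$counts >= 0))
  expect_true(all(co$counts == round(co$counts)))
  expect_true(all(co$log_tpm >= 0))
  expect_equal(table(co$truth_genes$sign)[["1"]], 15)
  expect_equal(table(co$truth_genes$sign)[["-1"]], 15)
})

test_that("missing_rate removes one source per affected line", {
  cfg <- synth_config(n_genes = 100, missing_rate = 0.2, seed = 5)
  co <- simulate_cohort(cfg)
  n <- 150
  n_complete <- length(Reduce(intersect, list(co$ic50_a$id, co$ic50_b$id,
                                              colnames(co$counts))))
  expect_equal(n_complete, n - floor(0.2 * n))
  merged <- merge_cohort(co$ic50_a, co$ic50_b, co$counts, co$log_tpm)
  expect_equal(length(merged$sample_ids), n_complete)
})

test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- synth_config(n_genes = 150, seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$log_tpm, b$log_tpm)
  expect_identical(a$ic50_a, b$ic50_a)
  expect_false(identical(
    simulate_cohort(synth_config(n_genes = 150, seed = 12))$counts,
    a$counts))
})

test_that("planted genes carry the configured log2 fold change", {
  # Monte-Carlo over 10 cohorts: class log2 mean-count ratio near planted
  lfcs <- sapply(1:10, function(s) {
    co <- simulate_cohort(synth_config(n_sensitive = 50, n_resistant = 50,
                                       n_discordant = 0, n_genes = 300,
                                       signature_log2fc = 1.5,
                                       nb_dispersion = 0.2, seed = s))
    res <- names(co$truth_labels)[co$truth_labels == "resistant"]
    sen <- names(co$truth_labels)[co$truth_labels == "sensitive"]
    up <- co$truth_genes$gene[co$truth_genes$sign == 1]
    mean(log2(rowMeans(co$counts[up, res]) / rowMeans(co$counts[up, sen])))
  })
  expect_true(all(abs(lfcs - 1.5) < 0.3))
})

test_that("counts match negative-binomial marginal moments", {
  cfg <- synth_config(n_sensitive = 400, n_resistant = 0, n_discordant = 0,
                      n_signature_up = 0, n_signature_down = 0,
                      n_genes = 400, nb_dispersion = 0.4,
                      libsize_log_sd = 0, seed = 2)
  co <- simulate_cohort(cfg)
  mu <- rowMeans(co$counts)
  v <- apply(co$counts, 1, var)
  alpha_hat <- (v - mu) / mu^2
  keep <- mu > 20
  expect_gt(sum(keep), 100)
  expect_equal(median(alpha_hat[keep]), 0.4, tolerance = 0.15)
})

test_that("config validation rejects impossible settings", {
  expect_error(synth_config(signature_log2fc = 0), "signature_log2fc")
  expect_error(synth_config(nb_dispersion = -1), "nb_dispersion")
  expect_error(synth_config(n_genes = 10, n_signature_up = 8,
                            n_signature_down = 8), "exceeds")
  expect_error(synth_config(missing_rate = 1), "missing_rate")
  expect_error(synth_config(n_sensitive = 0), "empty class")
})

test_that("survival times follow the group hazards", {
  groups <- setNames(rep(c("sensitive", "resistant"), each = 2000),
                     sprintf("P%04d", 1:4000))
  # censor_rate 0: every event observed
  tab <- simulate_survival(groups, hazard_ratio = 3, baseline_rate = 0.2,
                           censor_rate = 0, seed = 4)
  expect_true(all(tab$event == 1))
  med <- tapply(tab$time, tab$group, median)
  # exponential median ln2/lambda: resistant at 3x hazard has 1/3 median
  expect_equal(med[["resistant"]] / med[["sensitive"]], 1 / 3,
               tolerance = 0.12)
  # hazard_ratio 1: medians agree within Monte-Carlo error
  tab1 <- simulate_survival(groups, hazard_ratio = 1, censor_rate = 0,
                            seed = 5)
  med1 <- tapply(tab1$time, tab1$group, median)
  expect_equal(med1[["resistant"]] / med1[["sensitive"]], 1,
               tolerance = 0.12)
  # censoring fraction tracks censor_rate
  tabc <- simulate_survival(groups, hazard_ratio = 1, censor_rate = 0.3,
                            seed = 6)
  expect_equal(mean(tabc$event == 0), 0.3, tolerance = 0.05)
  expect_error(simulate_survival(groups, hazard_ratio = 0), "hazard_ratio")
})

test_that("drug panel plants per-drug class effects", {
  labels <- setNames(rep(c("sensitive", "resistant"), each = 40),
                     sprintf("C%03d", 1:80))
  panel <- simulate_drug_panel(labels,
                               drug_effects = c(null_drug = 0, hit_drug = 2),
                               noise_sd = 0.4, seed = 9)
  expect_identical(panel,
                   simulate_drug_panel(labels,
                                       drug_effects = c(null_drug = 0,
                                                        hit_drug = 2),
                                       noise_sd = 0.4, seed = 9))
  cmp <- drug_panel_compare(panel, labels)
  null_row <- cmp[cmp$drug == "null_drug", ]
  hit_row <- cmp[cmp$drug == "hit_drug", ]
  expect_gt(null_row$p, 0.05)
  expect_equal(null_row$fold_change, 1, tolerance = 0.25)
  expect_equal(hit_row$fold_change, 4, tolerance = 1)
  expect_lt(hit_row$p, 1e-6)
})
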