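# Candidate-panel intersection, standardized logistic coefficients,
# recursive specificity elimination and the panel correlation check.

test_that("sign intersection is plain set algebra", {
  p <- sign_intersection(c("a", "b"), c("c"), c("b", "c", "d"))
  expect_equal(p$up, "b")
  expect_equal(p$down, "c")
  expect_setequal(p$genes, c("b", "c"))
  expect_equal(length(sign_intersection("x", "y", "z")$genes), 0)
  full <- sign_intersection(c("a", "b"), c("c"), c("a", "b", "c", "q"))
  expect_setequal(full$genes, c("a", "b", "c"))
  expect_error(sign_intersection(c("a"), c("a"), "a"), "disjoint")
})

test_that("standardized coefficients are scale-invariant and calibrated", {
  fx <- make_feature_fixture(n_per_class = 250, n_inf = 1, n_noise = 9,
                             effect = 3, seed = 1)
  co <- standardized_logit_coefficients(fx$features, fx$labels)
  # the near-separating feature dominates
  expect_equal(names(which.max(abs(co))), fx$informative)
  # multiplying a raw feature by 10 leaves its standardized coefficient
  scaled <- fx$features
  scaled[3, ] <- scaled[3, ] * 10
  co2 <- standardized_logit_coefficients(scaled, fx$labels)
  expect_equal(co2, co, tolerance = 1e-9)
  # zero-variance feature: coefficient 0 with warning
  flat <- fx$features
  flat[2, ] <- 1
  expect_warning(co3 <- standardized_logit_coefficients(flat, fx$labels),
                 "zero-variance")
  expect_equal(unname(co3[2]), 0)
})

test_that("independent features have small coefficients at n = 500", {
  # a single label-independent feature (plus one companion) at n = 500
  co <- sapply(1:10, function(s) {
    fx <- make_feature_fixture(n_per_class = 250, n_inf = 0, n_noise = 2,
                               seed = s)
    standardized_logit_coefficients(fx$features, fx$labels)[1]
  })
  # null coefficients scale like 2/sqrt(n) ~ 0.09; typical magnitude < 0.1
  expect_lt(mean(abs(co)), 0.1)
  expect_true(all(abs(co) < 0.3))
})

test_that("ridge logistic matches the glmnet ridge path point", {
  skip_if_not_installed("glmnet")
  fx <- make_feature_fixture(n_per_class = 100, n_inf = 2, n_noise = 6,
                             effect = 1, seed = 3)
  X <- scale(t(fx$features))
  y <- as.integer(fx$labels[rownames(X)] == "resistant")
  C <- 1.0
  fit <- sensig:::ridge_logistic(X, y, C = C)
  # glmnet objective: (1/n) loss + lambda/2 ||w||^2  =>  lambda = 1/(n C)
  g <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                      lambda = 1 / (nrow(X) * C), standardize = FALSE,
                      thresh = 1e-14)
  expect_equal(unname(fit$coefficients),
               as.numeric(g$beta), tolerance = 1e-4)
  expect_equal(fit$intercept, as.numeric(g$a0), tolerance = 1e-4)
})

test_that("elimination trace walks from the full panel to one gene", {
  fx <- make_feature_fixture(n_per_class = 25, n_inf = 2, n_noise = 6,
                             effect = 2, seed = 4)
  tr <- recursive_specificity_elimination(fx$features, fx$labels, seed = 1)
  expect_equal(tr$trace$panel_size, 8:1)
  expect_true(all(tr$trace$mean_specificity >= 0 &
                    tr$trace$mean_specificity <= 1))
  expect_true(all(tr$trace$sd_specificity >= 0))
  # elimination order is a permutation of all but the final gene
  expect_equal(sort(c(tr$elimination_order, tr$panels[["1"]])),
               sort(rownames(fx$features)))
  # deterministic under the seed
  tr2 <- recursive_specificity_elimination(fx$features, fx$labels, seed = 1)
  expect_identical(tr$elimination_order, tr2$elimination_order)
  expect_identical(tr$trace, tr2$trace)
})

test_that("CV specificity equals the brute-force confusion count", {
  fx <- make_feature_fixture(n_per_class = 30, n_inf = 2, n_noise = 4,
                             effect = 1.5, seed = 5)
  fold <- sensig:::stratified_folds(fx$labels, 5, seed = 9)
  got <- sensig:::cv_specificity(fx$features, fx$labels, fold)
  expect_equal(got, oracle_cv_specificity(fx$features, fx$labels, fold),
               tolerance = 1e-9)
})

test_that("noise genes are eliminated before informative genes", {
  hits <- sapply(1:3, function(s) {
    fx <- make_feature_fixture(n_per_class = 100, n_inf = 5, n_noise = 45,
                               effect = 2, seed = s)
    tr <- recursive_specificity_elimination(fx$features, fx$labels,
                                            seed = s)
    first20 <- tr$elimination_order[1:20]
    mean(first20 %in% fx$noise)
  })
  expect_true(all(hits >= 0.8))
})

test_that("the optimal panel maximizes specificity with ties to more genes", {
  mk_trace <- function(spec) {
    sizes <- seq(length(spec), 1)
    structure(list(
      trace = data.frame(panel_size = sizes, mean_specificity = spec,
                         sd_specificity = 0,
                         eliminated_gene = c(letters[seq_len(length(spec) - 1)],
                                             NA)),
      panels = setNames(lapply(sizes, function(k) letters[1:k]),
                        as.character(sizes))),
      class = "elimination_trace")
  }
  # unique maximum
  expect_equal(length(optimal_panel(mk_trace(c(0.8, 0.95, 0.9, 0.7)))), 3)
  # all tie: the full panel is retained
  expect_equal(length(optimal_panel(mk_trace(rep(0.9, 4)))), 4)
  # monotone increasing specificity with size: full panel
  expect_equal(length(optimal_panel(mk_trace(c(0.9, 0.8, 0.7, 0.6)))), 4)
})

test_that("panel correlation is symmetric with unit diagonal", {
  fx <- make_feature_fixture(n_per_class = 250, n_inf = 0, n_noise = 10,
                             seed = 6)
  pc <- panel_correlation(fx$features)
  expect_identical(pc$matrix, t(pc$matrix))
  expect_equal(unname(diag(pc$matrix)), rep(1, 10))
  expect_lt(pc$max_abs_offdiag, 0.25)
  # duplicated gene shows r = 1
  dup <- rbind(fx$features, dup = fx$features[1, ])
  expect_equal(panel_correlation(dup)$max_abs_offdiag, 1)
  # zero-variance gene reported missing
  flat <- fx$features
  flat[2, ] <- 2
  pcf <- panel_correlation(flat)
  expect_true(all(is.na(pcf$matrix[2, ])))
})
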