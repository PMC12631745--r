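# Survival stratification and cross-drug statistics.

test_that("Kaplan-Meier reproduces the product-limit hand computation", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$curve$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$median, 2)
  # no censoring: curve equals the empirical survivor function
  set.seed(1)
  t <- rexp(40)
  km2 <- km_estimate(t, rep(1, 40))
  expect_equal(km2$curve$surv,
               sapply(sort(t), function(x) mean(t > x)))
  # all censored: flat at 1, median undefined
  km3 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km3$curve$surv == 1))
  expect_true(is.na(km3$median))
})

test_that("log-rank matches the event-time tabulation oracle", {
  # identical groups: statistic ~ 0
  t <- c(1, 2, 3, 4, 5); e <- c(1, 1, 0, 1, 1)
  same <- logrank_test(t, e, t, e)
  expect_equal(same$chisq, 0, tolerance = 1e-9)
  expect_equal(same$p, 1, tolerance = 1e-6)
  # 4-patient hand example
  got <- logrank_test(c(1, 3), c(1, 1), c(2, 4), c(1, 0))
  expect_equal(got$chisq,
               oracle_logrank(c(1, 3), c(1, 1), c(2, 4), c(1, 0)),
               tolerance = 1e-9)
  # larger random instances against the oracle, and group symmetry
  set.seed(2)
  for (i in 1:5) {
    ta <- rexp(30); tb <- rexp(35, 1.8)
    ea <- rbinom(30, 1, 0.8); eb <- rbinom(35, 1, 0.8)
    if (sum(ea) + sum(eb) == 0) next
    g <- logrank_test(ta, ea, tb, eb)
    expect_equal(g$chisq, oracle_logrank(ta, ea, tb, eb), tolerance = 1e-9)
    expect_equal(g$chisq, logrank_test(tb, eb, ta, ea)$chisq,
                 tolerance = 1e-9)
  }
  # no events at all: undefined, reported
  none <- logrank_test(c(1, 2), c(0, 0), c(3, 4), c(0, 0))
  expect_true(is.na(none$chisq))
  expect_equal(none$reason, "no events")
})

test_that("Cox fit is calibrated at the null and flags single-level terms", {
  groups <- setNames(rep(c("sensitive", "resistant"), each = 500),
                     sprintf("P%04d", 1:1000))
  tab <- simulate_survival(groups, hazard_ratio = 1, censor_rate = 0.2,
                           seed = 3)
  set.seed(4)
  tab$noise_cov <- rnorm(1000)
  tab$single_level <- "M0"
  fit <- cox_fit(tab, c("noise_cov", "single_level"))
  hr <- fit$hazard_ratio[fit$term == "noise_cov"]
  expect_gt(hr, 0.8); expect_lt(hr, 1.25)
  m_row <- fit[fit$term == "single_level", ]
  expect_false(m_row$estimable)
  expect_true(is.na(m_row$hazard_ratio))
  # hazard ratio sits inside its own CI
  expect_true(fit$ci_low[1] <= hr && hr <= fit$ci_high[1])
})

test_that("Cox fit recovers a planted log hazard ratio", {
  errs <- sapply(1:3, function(s) {
    groups <- setNames(rep(c("sensitive", "resistant"), each = 500),
                       sprintf("P%04d", 1:1000))
    tab <- simulate_survival(groups, hazard_ratio = 2, censor_rate = 0.2,
                             seed = s)
    tab$resistant <- as.integer(tab$group == "resistant")
    fit <- cox_fit(tab, "resistant")
    log(fit$hazard_ratio[1]) - log(2)
  })
  expect_true(all(abs(errs) < 0.15))
})

test_that("landmark ROC applies the censoring exclusion rule", {
  times <- c(1, 3, 5, 7, 3)
  events <- c(1, 1, 0, 0, 0)
  scores <- c(0.9, 0.8, 0.2, 0.1, 0.5)
  # horizon 4: patients 1-2 positive, 3-4 negative, 5 censored early -> excluded
  lr <- landmark_roc(scores, times, events, horizon = 4)
  expect_equal(lr$auc, 1)
  expect_equal(lr$n_pos, 2)
  expect_equal(lr$n_neg, 2)
  expect_equal(lr$n_excluded, 1)
  # scores equal to the event indicator are perfect
  lr2 <- landmark_roc(c(1, 1, 0, 0), c(1, 2, 9, 9), c(1, 1, 0, 0), 5)
  expect_equal(lr2$auc, 1)
  # random scores hover at chance
  set.seed(5)
  t <- rexp(400); e <- rep(1, 400)
  lr3 <- landmark_roc(runif(400), t, e, horizon = median(t))
  expect_equal(lr3$auc, 0.5, tolerance = 0.1)
  # empty class reported, not fabricated
  lr4 <- landmark_roc(c(0.2, 0.3), c(10, 11), c(0, 0), horizon = 5)
  expect_true(is.na(lr4$auc))
})

test_that("Welch test matches the closed form and degenerate paths", {
  got <- welch_t_test(c(1, 2, 3), c(4, 5, 6))
  ora <- oracle_welch(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$t, ora$t, tolerance = 1e-9)
  expect_equal(got$df, ora$df, tolerance = 1e-9)
  expect_equal(got$p, ora$p, tolerance = 1e-9)
  same <- welch_t_test(c(2, 4, 6), c(2, 4, 6))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  const <- welch_t_test(c(3, 3, 3), c(3, 3, 3))
  expect_equal(const$p, 1)
  # near-equal-variance case agrees with the pooled test
  set.seed(6)
  x <- rnorm(40); y <- rnorm(40, 0.5)
  expect_equal(welch_t_test(x, y)$p,
               t.test(x, y, var.equal = TRUE)$p.value, tolerance = 0.05)
})

test_that("drug comparisons report geometric fold changes with log-scale CIs", {
  set.seed(7)
  labels <- setNames(rep(c("sensitive", "resistant"), each = 40),
                     sprintf("C%03d", 1:80))
  panel <- simulate_drug_panel(labels, c(shifted = 2, flat = 0, tiny = 1),
                               noise_sd = 0.5, seed = 8)
  panel[1:39, "tiny"] <- NA  # starve one arm
  cmp <- drug_panel_compare(panel, labels, bh_correct = TRUE)
  shifted <- cmp[cmp$drug == "shifted", ]
  expect_gt(shifted$fold_change, 3)
  expect_lt(shifted$fold_change, 5.4)
  # fold change always inside its own CI; log FC = difference of log means
  ok <- !cmp$skipped
  expect_true(all(cmp$ci_low[ok] <= cmp$fold_change[ok] &
                    cmp$fold_change[ok] <= cmp$ci_high[ok]))
  res <- names(labels)[labels == "resistant"]
  sen <- names(labels)[labels == "sensitive"]
  expect_equal(log(shifted$fold_change),
               mean(log(panel[res, "shifted"])) -
                 mean(log(panel[sen, "shifted"])), tolerance = 1e-12)
  flat <- cmp[cmp$drug == "flat", ]
  expect_true(flat$ci_low < 1 && flat$ci_high > 1)
  # starved drug is skipped with a reason, BH only over tested drugs
  expect_true(cmp$skipped[cmp$drug == "tiny"])
  expect_equal(cmp$padj[ok], bh_adjust(cmp$p[ok]))
})

test_that("fold-change concordance equals the closed-form correlation", {
  got <- foldchange_concordance(c(1, 2, 3), c(2, 4, 7))
  ora <- oracle_pearson(c(1, 2, 3), c(2, 4, 7))
  expect_equal(got$r, ora$r, tolerance = 1e-12)
  expect_equal(got$p, ora$p, tolerance = 1e-12)
  expect_equal(foldchange_concordance(1:5, 1:5)$r, 1)
  expect_equal(foldchange_concordance(1:5, -(1:5))$r, -1)
  flat <- foldchange_concordance(1:5, rep(2, 5))
  expect_true(is.na(flat$r))
})
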