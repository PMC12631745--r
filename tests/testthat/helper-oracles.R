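# Independent brute-force oracles used to cross-check the package's
# statistics. Each is written directly from the defining formula, not by
# calling the implementation under test.

# ROC AUC as the Mann-Whitney pair-ordering statistic: fraction of
# (positive, negative) pairs ordered correctly, half credit for ties.
oracle_roc_auc <- function(scores, positive) {
  sp <- scores[positive]
  sn <- scores[!positive]
  total <- 0
  for (a in sp) for (b in sn) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(sp) * length(sn))
}

# Precision-recall AUC by naive per-threshold recomputation and
# trapezoidal integration, anchored at recall 0.
oracle_pr_auc <- function(scores, positive) {
  ths <- sort(unique(scores), decreasing = TRUE)
  rec <- prec <- numeric(length(ths))
  for (i in seq_along(ths)) {
    pred <- scores >= ths[i]
    rec[i] <- sum(pred & positive) / sum(positive)
    prec[i] <- sum(pred & positive) / sum(pred)
  }
  rec <- c(0, rec); prec <- c(prec[1], prec)
  sum(diff(rec) * (prec[-1] + prec[-length(prec)]) / 2)
}

# Mean silhouette from explicit distance loops.
oracle_silhouette <- function(points, labels) {
  n <- nrow(points)
  d <- function(i, j) sqrt(sum((points[i, ] - points[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(vapply(own, function(j) d(i, j), 1))
    b <- Inf
    for (k in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(vapply(which(labels == k), function(j) d(i, j), 1)))
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# BH step-up: sort ascending, p * n / rank, cumulative min from the
# largest, cap at 1, restore order.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- p[ord] * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(ord)]
}

# Welch t statistic and Welch-Satterthwaite df from the closed form.
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Pearson r from the closed form and its t-transform p.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

# Two-group log-rank chi-square by explicit event-time tabulation
# (observed minus expected in group A, hypergeometric variance).
oracle_logrank <- function(time_a, event_a, time_b, event_b) {
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp_a <- rep(c(TRUE, FALSE), c(length(time_a), length(time_b)))
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n_tot <- sum(at_risk); n_a <- sum(at_risk & grp_a)
    d_tot <- sum(time == t & event == 1)
    d_a <- sum(time == t & event == 1 & grp_a)
    o_minus_e <- o_minus_e + d_a - d_tot * n_a / n_tot
    if (n_tot > 1) {
      v <- v + d_tot * (n_a / n_tot) * (1 - n_a / n_tot) *
        (n_tot - d_tot) / (n_tot - 1)
    }
  }
  o_minus_e^2 / v
}

# Agglomerative Ward clustering by exhaustive pair search with the
# ward.D2 criterion: d(A, B) = sqrt(2|A||B|/(|A|+|B|)) * ||mean_A - mean_B||.
oracle_ward_heights <- function(points) {
  clusters <- lapply(seq_len(nrow(points)), function(i) i)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      a <- clusters[[i]]; b <- clusters[[j]]
      ca <- colMeans(points[a, , drop = FALSE])
      cb <- colMeans(points[b, , drop = FALSE])
      d <- sqrt(2 * length(a) * length(b) / (length(a) + length(b))) *
        sqrt(sum((ca - cb)^2))
      if (d < best_d) { best_d <- d; best <- c(i, j) }
    }
    heights <- c(heights, best_d)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  heights
}

# Confusion-count specificity of a standardized ridge-logistic model,
# recomputed per fold from scratch.
oracle_cv_specificity <- function(features, labels, fold, C = 1.0) {
  k <- max(fold)
  out <- numeric(k)
  for (f in seq_len(k)) {
    tr <- names(fold)[fold != f]
    te <- names(fold)[fold == f]
    Xtr <- t(features[, tr, drop = FALSE])
    ctr <- colMeans(Xtr); scl <- apply(Xtr, 2, sd); scl[scl == 0] <- 1
    fit <- sensig:::ridge_logistic(scale(Xtr, ctr, scl),
                                   as.integer(labels[tr] == "resistant"),
                                   C = C)
    Xte <- scale(t(features[, te, drop = FALSE]), ctr, scl)
    p <- 1 / (1 + exp(-(drop(Xte %*% fit$coefficients) + fit$intercept)))
    tn <- 0; fp <- 0
    for (i in seq_along(te)) {
      if (labels[te[i]] == "sensitive") {
        if (p[i] > 0.5) fp <- fp + 1 else tn <- tn + 1
      }
    }
    out[f] <- tn / (tn + fp)
  }
  out
}

# Small labeled feature fixture: `n_inf` informative genes with a given
# standardized effect plus `n_noise` pure-noise genes.
make_feature_fixture <- function(n_per_class = 50, n_inf = 5, n_noise = 45,
                                 effect = 2, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  ids <- sprintf("S%03d", seq_len(n))
  labels <- setNames(rep(c("sensitive", "resistant"), each = n_per_class),
                     ids)
  p <- n_inf + n_noise
  X <- matrix(rnorm(p * n), nrow = p,
              dimnames = list(sprintf("g%03d", seq_len(p)), ids))
  if (n_inf > 0) {
    X[seq_len(n_inf), labels == "resistant"] <-
      X[seq_len(n_inf), labels == "resistant"] + effect
  }
  list(features = X, labels = labels,
       informative = rownames(X)[seq_len(n_inf)],
       noise = rownames(X)[setdiff(seq_len(p), seq_len(n_inf))])
}
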