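# Phenotype derivation: Ward clustering of the two-source IC50 profile,
# silhouette-guided model selection, the cross-source consistency rule
# that turns clusters into sensitive/resistant labels, and the ANOVA /
# Tukey check that clusters differ in each source.

#' Ward hierarchical clustering of IC50 profiles
#'
#' Agglomerative clustering with Euclidean distances and Ward linkage
#' (`ward.D2`, the Ward criterion on untransformed distances), cut at a
#' fixed merge height.
#'
#' @param points Numeric matrix, samples in rows (typically two columns:
#'   IC50 from each source). Rownames are sample ids.
#' @param cut_distance Merge height above which links are removed
#'   (default 8).
#' @param log_transform Cluster `ln(IC50)` instead of raw values
#'   (default `FALSE`, matching IC50 plotted on the measurement scale).
#' @return List of class `cluster_assignment`: `labels` (named integer,
#'   contiguous from 1), `n_clusters`, `merge`, `height` (the linkage
#'   record), `silhouette` (mean silhouette, `NA` unless
#'   `2 <= k <= n - 1`), `cut_distance`.
#' @export
ward_cluster <- function(points, cut_distance = 8, log_transform = FALSE) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("need at least 2 points")
  if (any(!is.finite(points))) stop("non-finite coordinates in points")
  if (is.null(rownames(points))) rownames(points) <- seq_len(nrow(points))
  if (log_transform) points <- log(points)
  hc <- hclust(dist(points), method = "ward.D2")
  labels <- cutree(hc, h = cut_distance)
  k <- max(labels)
  sil <- if (k >= 2 && k <= nrow(points) - 1) {
    silhouette_mean(points, labels)
  } else {
    NA_real_
  }
  structure(list(labels = labels, n_clusters = k,
                 merge = hc$merge, height = hc$height,
                 silhouette = sil, cut_distance = cut_distance,
                 hclust = hc),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("Cluster assignment:", x$n_clusters, "clusters over",
      length(x$labels), "samples")
  if (!is.na(x$silhouette)) cat(sprintf(" (mean silhouette %.3f)", x$silhouette))
  cat("\n  sizes:", paste(tabulate(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' Mean silhouette score of a clustering
#'
#' For each sample, `s = (b - a) / max(a, b)` with `a` the mean distance
#' to its own cluster and `b` the smallest mean distance to another
#' cluster; samples in singleton clusters contribute 0. Returns the mean
#' over samples.
#'
#' @param points Numeric matrix, samples in rows.
#' @param labels Integer cluster labels, one per row; at least 2 distinct
#'   clusters, each non-empty.
#' @return Mean silhouette in `[-1, 1]`.
#' @export
silhouette_mean <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.integer(labels)
  if (length(labels) != nrow(points)) stop("labels must match rows of points")
  ks <- sort(unique(labels))
  if (length(ks) < 2) stop("silhouette undefined for fewer than 2 clusters")
  d <- as.matrix(dist(points))
  n <- nrow(points)
  s <- numeric(n)
  sizes <- tabulate(match(labels, ks))
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    n_own <- sum(own)
    if (n_own == 1) { s[i] <- 0; next }
    a <- sum(d[i, own]) / (n_own - 1)
    b <- min(vapply(ks[ks != labels[i]], function(k) {
      mean(d[i, labels == k])
    }, numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Silhouette-guided clustering model selection
#'
#' Evaluates the mean silhouette of hierarchical (Ward) and k-means
#' clusterings over a range of cluster counts and returns the selected
#' method and assignment. Hierarchical clustering is preferred whenever
#' its best silhouette is at least that of k-means (it yields the more
#' interpretable dendrogram); otherwise k-means wins.
#'
#' @param points Numeric matrix, samples in rows.
#' @param k_range Candidate cluster counts (default `2:10`, clipped to
#'   `n - 1`).
#' @param seed Seed for the k-means restarts (10 restarts, best inertia).
#' @param methods Methods to evaluate.
#' @return List: `method`, `k`, `assignment` (a `cluster_assignment`),
#'   `scores` (data frame method, k, silhouette), `best_k` (named vector,
#'   per-method best k).
#' @export
choose_clustering <- function(points, k_range = 2:10, seed = 1,
                              methods = c("hierarchical", "kmeans")) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (any(!is.finite(points))) stop("non-finite coordinates in points")
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (length(k_range) == 0) stop("k_range empty after clipping to 2..n-1")
  if (all(dist(points) == 0)) {
    stop("all points identical: clustering undefined (zero distances)")
  }
  if (is.null(rownames(points))) rownames(points) <- seq_len(nrow(points))
  hc <- hclust(dist(points), method = "ward.D2")
  scores <- data.frame(method = character(0), k = integer(0),
                       silhouette = numeric(0))
  assignments <- list()
  for (method in methods) {
    for (k in k_range) {
      labels <- if (method == "hierarchical") {
        cutree(hc, k = k)
      } else {
        with_seed(seed + k, kmeans(points, centers = k, nstart = 10,
                                   iter.max = 100)$cluster)
      }
      if (length(unique(labels)) < 2) next
      sil <- silhouette_mean(points, labels)
      scores <- rbind(scores, data.frame(method = method, k = k,
                                         silhouette = sil))
      assignments[[paste(method, k)]] <- labels
    }
  }
  if (nrow(scores) == 0) stop("no valid clustering found in k_range")
  best_k <- vapply(unique(scores$method), function(m) {
    sub <- scores[scores$method == m, ]
    sub$k[which.max(sub$silhouette)]
  }, integer(1))
  best_sil <- vapply(unique(scores$method), function(m) {
    max(scores$silhouette[scores$method == m])
  }, numeric(1))
  method <- if ("hierarchical" %in% names(best_sil) &&
                best_sil["hierarchical"] >= max(best_sil)) {
    "hierarchical"
  } else {
    names(best_sil)[which.max(best_sil)]
  }
  k <- best_k[[method]]
  labels <- assignments[[paste(method, k)]]
  assignment <- structure(
    list(labels = labels, n_clusters = k,
         merge = if (method == "hierarchical") hc$merge else NULL,
         height = if (method == "hierarchical") hc$height else NULL,
         silhouette = scores$silhouette[scores$method == method &
                                          scores$k == k],
         cut_distance = NA_real_,
         hclust = if (method == "hierarchical") hc else NULL),
    class = "cluster_assignment")
  list(method = method, k = k, assignment = assignment,
       scores = scores, best_k = best_k)
}

#' Derive sensitivity labels from clusters by cross-source consistency
#'
#' Ranks every sample's IC50 within each source, averages ranks per
#' cluster, and labels the cluster with the highest mean rank in *both*
#' sources resistant and the one with the lowest mean rank in both
#' sources sensitive. All other clusters are excluded as cross-source
#' inconsistent.
#'
#' @param assignment A `cluster_assignment` (or named integer labels).
#' @param ic50_a,ic50_b Named numeric IC50 vectors covering the clustered
#'   samples.
#' @return List of class `sensitivity_labels`: `labels` (named character
#'   `"sensitive"`/`"resistant"`), `excluded` (character ids),
#'   `source_cluster` (cluster index per class), `rank_table` (per-cluster
#'   mean ranks).
#' @export
assign_sensitivity <- function(assignment, ic50_a, ic50_b) {
  cl <- if (inherits(assignment, "cluster_assignment")) {
    assignment$labels
  } else {
    assignment
  }
  ids <- names(cl)
  if (is.null(ids)) stop("cluster labels must be named by sample id")
  if (length(unique(cl)) < 2) stop("need at least 2 clusters")
  if (!all(ids %in% names(ic50_a)) || !all(ids %in% names(ic50_b))) {
    stop("ic50 vectors must cover all clustered samples")
  }
  ra <- rank(ic50_a[ids])
  rb <- rank(ic50_b[ids])
  ks <- sort(unique(cl))
  rank_table <- data.frame(
    cluster = ks,
    n = as.vector(table(cl)[as.character(ks)]),
    mean_rank_a = vapply(ks, function(k) mean(ra[cl == k]), numeric(1)),
    mean_rank_b = vapply(ks, function(k) mean(rb[cl == k]), numeric(1)))
  hi_a <- ks[which.max(rank_table$mean_rank_a)]
  hi_b <- ks[which.max(rank_table$mean_rank_b)]
  lo_a <- ks[which.min(rank_table$mean_rank_a)]
  lo_b <- ks[which.min(rank_table$mean_rank_b)]
  if (hi_a != hi_b || lo_a != lo_b || hi_a == lo_a) {
    stop("no cluster is consistently extreme in both sources:\n",
         paste(utils::capture.output(print(rank_table)), collapse = "\n"))
  }
  labels <- character(0)
  res_ids <- ids[cl == hi_a]
  sen_ids <- ids[cl == lo_a]
  labels <- setNames(c(rep(.positive_class, length(res_ids)),
                       rep(.negative_class, length(sen_ids))),
                     c(res_ids, sen_ids))
  labels <- labels[order(names(labels))]
  excluded <- sort(setdiff(ids, names(labels)))
  structure(list(labels = labels, excluded = excluded,
                 source_cluster = c(sensitive = lo_a, resistant = hi_a),
                 rank_table = rank_table),
            class = "sensitivity_labels")
}

#' @export
print.sensitivity_labels <- function(x, ...) {
  cat("Sensitivity labels:",
      sum(x$labels == .negative_class), "sensitive,",
      sum(x$labels == .positive_class), "resistant,",
      length(x$excluded), "excluded (cross-source inconsistent)\n")
  invisible(x)
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Fixed-effects F test that per-cluster means differ, with Tukey honest
#' significant difference adjusted p-values for every cluster pair.
#'
#' @param values Numeric vector (e.g. one source's IC50).
#' @param labels Group labels aligned with `values`; at least 2 groups
#'   with at least 2 members each.
#' @return List: `F`, `p`, `pairwise` (data frame `comparison`, `diff`,
#'   `p_adj`).
#' @export
anova_tukey <- function(values, labels) {
  g <- factor(labels)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs at least 2 members")
  n <- length(values)
  k <- nlevels(g)
  means <- tapply(values, g, mean)
  grand <- mean(values)
  ssb <- sum(tapply(values, g, length) * (means - grand)^2)
  ssw <- sum((values - means[g])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  if (msw == 0) {
    if (msb == 0) {
      return(list(F = 0, p = 1,
                  pairwise = data.frame(comparison = character(0),
                                        diff = numeric(0),
                                        p_adj = numeric(0))))
    }
    Fstat <- Inf; p <- 0
  } else {
    Fstat <- msb / msw
    p <- pf(Fstat, k - 1, n - k, lower.tail = FALSE)
  }
  tk <- TukeyHSD(aov(values ~ g))$g
  pairwise <- data.frame(comparison = rownames(tk),
                         diff = tk[, "diff"],
                         p_adj = tk[, "p adj"],
                         row.names = NULL)
  list(F = Fstat, p = p, pairwise = pairwise)
}

#' Write sensitivity labels as delimited text
#'
#' @param labels A `sensitivity_labels` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "sensitivity_labels"))
  df <- rbind(data.frame(id = names(labels$labels),
                         class = unname(labels$labels),
                         excluded = FALSE),
              if (length(labels$excluded) > 0) {
                data.frame(id = labels$excluded, class = NA_character_,
                           excluded = TRUE)
              })
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
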