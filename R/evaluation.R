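#' One-vs-rest classification metrics for mapped cluster labels
#'
#' Scores a clustering-as-classifier result: for every category,
#' precision `TP / (TP + FP)`, recall (sensitivity) `TP / (TP + FN)` and
#' F1 `2TP / (2TP + FP + FN)` under one-vs-rest counting. Predictions
#' outside the category vocabulary (e.g. `"unassigned"` density noise)
#' are counted as missed detections (FN) for their true category and are
#' never true positives. Zero-denominator cases return 0 by convention.
#'
#' @param predicted character vector of predicted categories.
#' @param truth vector/factor of true categories, same length.
#' @return an object of class `metrics_report`: `per_class` data frame
#'   (category, tp, fp, fn, tn, precision, recall, f1), `macro` (named
#'   vector of macro-averaged precision/recall/f1), `median_iqr` (matrix
#'   of Tukey median and hinge-IQR per metric), `accuracy`.
#' @export
classification_metrics <- function(predicted, truth) {
  .assert(length(predicted) == length(truth), "length mismatch")
  n <- length(truth)
  cats <- if (is.factor(truth)) levels(truth) else {
    u <- unique(as.character(truth))
    known <- FRAME_CATEGORIES[FRAME_CATEGORIES %in% u]
    c(known, sort(setdiff(u, known)))
  }
  predicted <- as.character(predicted)
  truth <- as.character(truth)
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  rows <- lapply(cats, function(g) {
    tp <- sum(predicted == g & truth == g)
    fp <- sum(predicted == g & truth != g)
    fn <- sum(predicted != g & truth == g)
    tn <- n - tp - fp - fn
    data.frame(category = g, tp = tp, fp = fp, fn = fn, tn = tn,
               precision = safe_div(tp, tp + fp),
               recall = safe_div(tp, tp + fn),
               f1 = safe_div(2 * tp, 2 * tp + fp + fn))
  })
  per_class <- do.call(rbind, rows)
  macro <- c(precision = mean(per_class$precision),
             recall = mean(per_class$recall),
             f1 = mean(per_class$f1))
  mi <- sapply(c("precision", "recall", "f1"), function(m)
    median_and_iqr(per_class[[m]]))
  structure(list(per_class = per_class, macro = macro, median_iqr = mi,
                 accuracy = mean(predicted == truth)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 2, ...) {
  tab <- x$per_class[, c("category", "precision", "recall", "f1")]
  tab[-1] <- round(tab[-1], digits)
  print(tab, row.names = FALSE)
  cat("median :", paste(sprintf("%s %.2f", colnames(x$median_iqr),
                                x$median_iqr["median", ]),
                        collapse = ", "), "\n")
  cat("IQR    :", paste(sprintf("%s %.2f", colnames(x$median_iqr),
                                x$median_iqr["iqr", ]),
                        collapse = ", "), "\n")
  cat("overall accuracy:", round(x$accuracy, digits + 1), "\n")
  invisible(x)
}

#' Median and Tukey-hinge interquartile range
#'
#' The summary convention used for per-class metric tables: the standard
#' midpoint median, and an IQR computed as upper hinge minus lower hinge
#' with Tukey hinges (each half of the sorted data includes the median
#' when the length is odd). This is the quartile convention under which
#' four per-class values like (0.83, 0.91, 0.62, 0.85) summarize to
#' median 0.84 and IQR 0.16.
#'
#' @param values numeric vector, length >= 2.
#' @return named vector `c(median = ..., iqr = ...)`.
#' @export
median_and_iqr <- function(values) {
  .assert(is.numeric(values) && length(values) >= 2,
          "need at least two values")
  fn <- fivenum(values)
  c(median = fn[3], iqr = fn[4] - fn[2])
}

#' One-vs-rest ROC AUC from a score matrix
#'
#' Computes, per category, the area under the ROC curve via the rank
#' (Mann-Whitney) statistic with midranks for ties, plus the unweighted
#' mean across categories.
#'
#' @param scores numeric `N x G` matrix, one column per category, higher =
#'   more confident; column names give the category vocabulary.
#' @param truth vector/factor of true categories.
#' @return list with `per_class` (named numeric AUC vector) and `mean_auc`.
#' @export
roc_auc <- function(scores, truth) {
  .assert(is.matrix(scores) && nrow(scores) == length(truth),
          "scores must be an N x G matrix aligned with truth")
  cats <- colnames(scores)
  .assert(!is.null(cats), "scores must have category column names")
  truth <- as.character(truth)
  .assert(all(cats %in% truth), "a category is absent from truth")
  auc <- vapply(cats, function(g) {
    pos <- truth == g
    r <- rank(scores[, g])                    # midranks
    n1 <- sum(pos); n0 <- sum(!pos)
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
  list(per_class = auc, mean_auc = mean(auc))
}

#' Per-category confidence scores from a hard clustering
#'
#' ROC analysis needs graded scores, but a clustering yields only hard
#' assignments. The score of frame `x` for category `g` is the negative
#' Euclidean distance from `x` to the centroid (in the clustering space)
#' of the cluster mapped to `g`, standardized per category. Deterministic
#' and monotone in proximity to the mapped cluster.
#'
#' @param x the projection the clustering was run on.
#' @param clusters a `cluster_result`.
#' @param mapping a `label_mapping`.
#' @return numeric `N x G` score matrix with category column names.
#' @export
cluster_scores <- function(x, clusters, mapping) {
  proj <- as_projection(x)
  X <- proj$values
  cats <- unname(mapping$map)
  centroids <- t(vapply(names(mapping$map), function(cl) {
    members <- clusters$labels == as.integer(cl)
    colMeans(X[members, , drop = FALSE])
  }, numeric(ncol(X))))
  sc <- -sqrt(pmax(.sqdist(X, centroids), 0))
  colnames(sc) <- cats
  sc <- scale(sc)                              # per-category shift/scale
  sc[, unique(cats), drop = FALSE]
}

#' Average silhouette score
#'
#' Per-point silhouette `s = (b - a) / max(a, b)` with `a` the mean
#' distance to other points of the same cluster and `b` the smallest mean
#' distance to the points of any other cluster; points in singleton
#' clusters score 0. Density-noise points (-1) are excluded.
#'
#' @param x projection or matrix of points.
#' @param labels cluster labels aligned with rows.
#' @return list with `average` and `per_point` silhouettes (in `[-1, 1]`).
#' @export
silhouette_score <- function(x, labels) {
  X <- as_projection(x)$values
  labels <- if (inherits(labels, "cluster_result")) labels$labels
            else as.integer(labels)
  keep <- labels != -1L
  X <- X[keep, , drop = FALSE]
  labels <- labels[keep]
  uniq <- unique(labels)
  .assert(length(uniq) >= 2, "silhouette requires at least two clusters")
  D <- as.matrix(dist(X))
  n <- nrow(X)
  sizes <- table(labels)
  # mean distance from every point to every cluster, via indicator algebra
  member <- vapply(uniq, function(u) as.numeric(labels == u), numeric(n))
  sums <- D %*% member                         # n x K total distances
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- match(labels[i], uniq)
    n_own <- sizes[[as.character(labels[i])]]
    if (n_own <= 1) { s[i] <- 0; next }
    a <- sums[i, own] / (n_own - 1)
    b <- min(vapply(seq_along(uniq)[-own], function(j)
      sums[i, j] / sizes[[as.character(uniq[j])]], numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  list(average = mean(s), per_point = s)
}

#' Calinski-Harabasz index
#'
#' Variance-ratio criterion `CH = (BGSS / (K - 1)) / (WGSS / (N - K))`,
#' with `BGSS` the size-weighted squared distances of cluster centroids
#' from the global centroid and `WGSS` the within-cluster squared
#' distances from each point to its centroid; centroids are arithmetic
#' means. Larger values indicate better-separated clusterings.
#'
#' @param x projection or matrix of points.
#' @param labels cluster labels aligned with rows (noise -1 excluded).
#' @return CH score (positive; `Inf` with a warning when `WGSS = 0`).
#' @export
calinski_harabasz <- function(x, labels) {
  X <- as_projection(x)$values
  labels <- if (inherits(labels, "cluster_result")) labels$labels
            else as.integer(labels)
  keep <- labels != -1L
  X <- X[keep, , drop = FALSE]
  labels <- labels[keep]
  n <- nrow(X)
  uniq <- unique(labels)
  K <- length(uniq)
  .assert(K >= 2 && K < n, "require 2 <= K < N")
  grand <- colMeans(X)
  bgss <- 0; wgss <- 0
  for (u in uniq) {
    pts <- X[labels == u, , drop = FALSE]
    ctr <- colMeans(pts)
    bgss <- bgss + nrow(pts) * sum((ctr - grand)^2)
    wgss <- wgss + sum(sweep(pts, 2, ctr)^2)
  }
  if (wgss == 0) {
    warning("WGSS is zero; returning Inf")
    return(Inf)
  }
  (bgss / (K - 1)) / (wgss / (n - K))
}

#' Determine the number of clusters by a Calinski-Harabasz sweep
#'
#' Clusters the data at every candidate `k`, scores each partition with
#' the Calinski-Harabasz index and returns the argmax (ties break to the
#' smallest `k`).
#'
#' @param x projection or matrix of points.
#' @param k_range candidate cluster counts (default `2:6`).
#' @param method clustering method used for the sweep (default
#'   `"kmeans"`).
#' @param params extra clustering parameters.
#' @param seed seed forwarded to the clusterer.
#' @return list with `chosen_k` and `scores` (data frame of k and CH).
#' @export
determine_cluster_number <- function(x, k_range = 2:6, method = "kmeans",
                                     params = list(), seed = 42) {
  .assert(length(k_range) >= 1, "empty k_range")
  proj <- as_projection(x)
  .assert(all(k_range >= 2 & k_range < nrow(proj$values)),
          "k_range must lie in [2, N - 1]")
  ch <- vapply(k_range, function(k) {
    res <- cluster_features(proj, method = method,
                            params = modifyList(params,
                                                list(n_clusters = k)),
                            seed = seed)
    calinski_harabasz(proj, res)
  }, numeric(1))
  list(chosen_k = as.integer(k_range[which.max(ch)]),
       scores = data.frame(k = as.integer(k_range), ch = ch))
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided exact signed-rank test for small paired samples: zero
#' differences are dropped, absolute differences are midranked, the test
#' statistic is the smaller of the positive and negative signed-rank
#' sums, and the p-value is `2 * P(W <= w)` under exhaustive enumeration
#' of all `2^n` sign assignments (capped at 1). Suited to the n = 4
#' per-class comparisons of frame-triage recall tables, where asymptotic
#' approximations are meaningless.
#'
#' @param a,b paired numeric vectors, equal length, `2 <= n <= 15`.
#' @return list with `p_value`, `statistic` (smaller rank sum), `n_used`
#'   (pairs after dropping zeros) and `all_zero` flag.
#' @export
wilcoxon_exact <- function(a, b) {
  .assert(length(a) == length(b), "paired vectors must have equal length")
  .assert(length(a) >= 2 && length(a) <= 15, "supported for 2 <= n <= 15")
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0)
    return(list(p_value = 1, statistic = 0, n_used = 0L, all_zero = TRUE))
  n <- length(d)
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  w <- min(w_pos, w_neg)
  m <- 2^n
  signs <- vapply(seq_len(n),
                  function(i) bitwAnd(0:(m - 1), 2^(i - 1)) > 0,
                  logical(m))
  sums <- as.vector(signs %*% r)               # rank sum of each assignment
  p <- min(1, 2 * mean(sums <= w))
  list(p_value = p, statistic = w, n_used = n, all_zero = FALSE)
}
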