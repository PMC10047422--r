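# squared Euclidean distances between rows of X and rows of C
#' @noRd
.sqdist <- function(X, C) {
  outer(rowSums(X^2), rowSums(C^2), "+") - 2 * tcrossprod(X, C)
}

# k-means++ seeding
#' @noRd
.kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- pmax(.sqdist(X, centers[1, , drop = FALSE])[, 1], 0)
  for (j in seq_len(k - 1)) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1, ] <- X[sample.int(n, 1, prob = probs), ]
    d2 <- pmin(d2, pmax(.sqdist(X, centers[j + 1, , drop = FALSE])[, 1], 0))
  }
  centers
}

# Mini-batch k-means (Sculley-style): k-means++ seeding, per-center
# count-based learning rates, random mini-batches; best of n_init restarts
# by the full squared-error objective. With batch_size >= N every pass sees
# all points, recovering plain Lloyd behaviour.
#' @noRd
.minibatch_kmeans <- function(X, k, batch_size = 1024, max_iter = 100,
                              n_init = 3) {
  n <- nrow(X)
  batch_size <- min(batch_size, n)
  best <- NULL
  for (init in seq_len(n_init)) {
    centers <- .kmeanspp_init(X, k)
    counts <- rep(0, k)
    for (it in seq_len(max_iter)) {
      idx <- if (batch_size >= n) seq_len(n) else sample.int(n, batch_size)
      B <- X[idx, , drop = FALSE]
      assign <- max.col(-.sqdist(B, centers))
      for (j in unique(assign)) {
        members <- B[assign == j, , drop = FALSE]
        m <- nrow(members)
        # closed form of m sequential count-based updates with rate 1/count
        centers[j, ] <- (counts[j] * centers[j, ] + colSums(members)) /
          (counts[j] + m)
        counts[j] <- counts[j] + m
      }
    }
    lab <- max.col(-.sqdist(X, centers))
    # reseat empty clusters on the farthest points
    for (j in which(tabulate(lab, k) == 0)) {
      far <- which.max(rowSums((X - centers[lab, , drop = FALSE])^2))
      centers[j, ] <- X[far, ]
      lab <- max.col(-.sqdist(X, centers))
    }
    sse <- cluster_sse(X, lab)
    if (is.null(best) || sse < best$sse)
      best <- list(labels = lab, centers = centers, sse = sse)
  }
  best
}

#' Squared-error clustering objective
#'
#' The within-cluster sum of squared Euclidean distances to cluster
#' centroids — the objective minimized by k-means. Noise labels (-1) are
#' excluded.
#'
#' @param X numeric matrix of points.
#' @param labels integer cluster labels aligned with rows (noise = -1).
#' @return total squared error (numeric scalar).
#' @export
cluster_sse <- function(X, labels) {
  keep <- labels != -1
  X <- X[keep, , drop = FALSE]
  labels <- labels[keep]
  sse <- 0
  for (j in unique(labels)) {
    pts <- X[labels == j, , drop = FALSE]
    ctr <- colMeans(pts)
    sse <- sse + sum(sweep(pts, 2, ctr)^2)
  }
  sse
}

# Unnormalized-Laplacian spectral clustering: similarity graph (symmetrized
# kNN or RBF), L = D - W, k smallest eigenvectors, k-means on the rows.
#' @noRd
.spectral_cluster <- function(X, k, affinity = "nearest_neighbors",
                              n_neighbors = 10, gamma = NULL) {
  n <- nrow(X)
  D2 <- pmax(.sqdist(X, X), 0)
  if (affinity == "rbf") {
    if (is.null(gamma)) {
      med <- median(sqrt(D2[upper.tri(D2)]))
      gamma <- 1 / max(2 * med^2, .Machine$double.eps)
    }
    W <- exp(-gamma * D2)
    diag(W) <- 0
  } else {
    n_neighbors <- min(n_neighbors, n - 1)
    W <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nb <- order(D2[i, ])[2:(n_neighbors + 1)]
      W[i, nb] <- 1
    }
    W <- pmax(W, t(W))                      # mutual symmetrization
  }
  L <- diag(rowSums(W)) - W
  eg <- eigen(L, symmetric = TRUE)
  U <- eg$vectors[, n:(n - k + 1), drop = FALSE]   # k smallest eigenvalues
  stats::kmeans(U, centers = k, nstart = 10, iter.max = 50)$cluster
}

# Textbook DBSCAN over a precomputed neighborhood (core point: at least
# min_pts points, self included, within eps); noise labeled -1.
#' @noRd
.dbscan_cluster <- function(X, eps, min_pts) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  nbrs <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nbrs, length, integer(1)) >= min_pts
  labels <- rep(-2L, n)                     # -2 = unvisited
  cl <- -1L
  for (i in seq_len(n)) {
    if (labels[i] != -2L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nbrs[[i]], i)
    while (length(queue)) {
      q <- queue[1]
      queue <- queue[-1]
      if (labels[q] == -1L) labels[q] <- cl        # border, was noise
      if (labels[q] != -2L) next
      labels[q] <- cl
      if (core[q]) queue <- union(queue, setdiff(nbrs[[q]], q))
    }
  }
  labels[labels == -2L] <- -1L
  labels
}

#' Cluster projected features
#'
#' Runs one of the four clustering families over a projection with a
#' uniform result contract: integer labels starting at 0, with -1 reserved
#' for density-method noise.
#'
#' * `"kmeans"`: mini-batch k-means (k-means++ seeding, count-based
#'   per-center learning rates, best of `n_init` restarts by the
#'   squared-error objective). Params: `n_clusters`, `batch_size`
#'   (default `min(1024, N)`), `max_iter` (100), `n_init` (3).
#' * `"agglomerative"`: hierarchical merging via [stats::hclust()] cut at
#'   `n_clusters`. Params: `n_clusters`, `linkage` in `ward` (default),
#'   `average`, `complete`, `single`.
#' * `"spectral"`: unnormalized graph Laplacian of a similarity graph,
#'   k-means on the smallest-eigenvalue eigenvectors. Params: `n_clusters`,
#'   `affinity` in `nearest_neighbors` (default) / `rbf`, `n_neighbors`
#'   (10), `gamma` (median-distance heuristic).
#' * `"dbscan"`: density-based clustering; density-unreachable points get
#'   label -1. Params: `eps` (> 0), `min_pts` (>= 1; a point is core when
#'   at least `min_pts` points, itself included, lie within `eps`).
#'
#' All methods use Euclidean distance and are deterministic given `seed`.
#'
#' @param x a `frame_projection`, `frame_embedding` or numeric matrix.
#' @param method one of `"kmeans"`, `"agglomerative"`, `"spectral"`,
#'   `"dbscan"`.
#' @param params named list of method parameters (see above).
#' @param seed integer seed.
#' @return an object of class `cluster_result`: `labels` (integer, length
#'   N), `method`, `params`, `k_found` (distinct non-noise clusters),
#'   `frame_ids`, and `centers` for centroid-based methods.
#' @export
cluster_features <- function(x, method = c("kmeans", "agglomerative",
                                           "spectral", "dbscan"),
                             params = list(), seed = 42) {
  method <- match.arg(method)
  proj <- as_projection(x)
  X <- proj$values
  n <- nrow(X)
  centers <- NULL

  if (method %in% c("kmeans", "agglomerative", "spectral")) {
    k <- params$n_clusters
    .assert(!is.null(k), sprintf("method '%s' requires params$n_clusters",
                                 method))
    .assert(k >= 1 && k <= n, "n_clusters must lie in [1, N]")
  }

  if (method == "kmeans") {
    k <- params$n_clusters
    bs <- if (is.null(params$batch_size)) min(1024, n) else params$batch_size
    mi <- if (is.null(params$max_iter)) 100 else params$max_iter
    ni <- if (is.null(params$n_init)) 3 else params$n_init
    fit <- withr::with_seed(seed,
      .minibatch_kmeans(X, k, batch_size = bs, max_iter = mi, n_init = ni))
    labels <- fit$labels - 1L
    centers <- fit$centers
    used <- list(n_clusters = k, batch_size = bs, max_iter = mi, n_init = ni)
  } else if (method == "agglomerative") {
    k <- params$n_clusters
    linkage <- if (is.null(params$linkage)) "ward" else params$linkage
    .assert(linkage %in% c("ward", "average", "complete", "single"),
            "linkage must be ward, average, complete or single")
    hc_method <- c(ward = "ward.D2", average = "average",
                   complete = "complete", single = "single")[[linkage]]
    labels <- cutree(hclust(dist(X), method = hc_method), k = k) - 1L
    used <- list(n_clusters = k, linkage = linkage)
  } else if (method == "spectral") {
    k <- params$n_clusters
    affinity <- if (is.null(params$affinity)) "nearest_neighbors"
                else params$affinity
    .assert(affinity %in% c("nearest_neighbors", "rbf"),
            "affinity must be nearest_neighbors or rbf")
    nb <- if (is.null(params$n_neighbors)) 10 else params$n_neighbors
    labels <- withr::with_seed(seed,
      .spectral_cluster(X, k, affinity = affinity, n_neighbors = nb,
                        gamma = params$gamma)) - 1L
    used <- list(n_clusters = k, affinity = affinity, n_neighbors = nb,
                 gamma = params$gamma)
  } else {
    .assert(!is.null(params$eps) && params$eps > 0,
            "dbscan requires params$eps > 0")
    .assert(!is.null(params$min_pts) && params$min_pts >= 1,
            "dbscan requires params$min_pts >= 1")
    labels <- .dbscan_cluster(X, eps = params$eps, min_pts = params$min_pts)
    used <- list(eps = params$eps, min_pts = params$min_pts)
  }

  k_found <- length(unique(labels[labels != -1]))
  if (is.null(centers) && k_found >= 1) {
    centers <- t(vapply(sort(unique(labels[labels != -1])), function(j)
      colMeans(X[labels == j, , drop = FALSE]), numeric(ncol(X))))
  }
  structure(list(labels = as.integer(labels), method = method, params = used,
                 k_found = as.integer(max(k_found, 1L)),
                 centers = centers, frame_ids = proj$frame_ids),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result:", x$method, "| k_found:", x$k_found,
      "| noise:", sum(x$labels == -1), "\n")
  print(table(x$labels))
  invisible(x)
}
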