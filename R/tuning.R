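#' Partition-method tuning cost
#'
#' The hyperparameter-search cost for the partition-style clustering
#' methods (mini-batch k-means, agglomerative, spectral):
#' `C = (1 - S_rec) + 0.1 * |S_rec - S_pre|`, where `S_rec` and `S_pre`
#' are the macro-averaged recall and precision obtained after automatic
#' cluster labeling. Minimal (0) exactly at perfect, balanced performance.
#'
#' @param s_rec macro-averaged recall in `[0, 1]`.
#' @param s_pre macro-averaged precision in `[0, 1]`.
#' @return cost (numeric scalar, >= 0).
#' @export
cost_partition <- function(s_rec, s_pre) {
  .assert(is.numeric(s_rec) && is.numeric(s_pre) &&
          all(s_rec >= 0 & s_rec <= 1) && all(s_pre >= 0 & s_pre <= 1),
          "s_rec and s_pre must lie in [0, 1]")
  (1 - s_rec) + 0.1 * abs(s_rec - s_pre)
}

#' Density-method tuning cost
#'
#' The hyperparameter-search cost for DBSCAN, which has no cluster-count
#' parameter: `C = N_out + (1 - beta) * (alpha * |N_in - K|) + beta * sigma`
#' where `N_out` is the number of noise points (label -1), `N_in` the
#' number of distinct non-noise clusters, and `sigma` the mean squared
#' deviation of each non-noise cluster's size from `n_target`. With the
#' defaults (`alpha = 100`, `beta = 0.01`, `K = 4`, `n_target = 180`) a
#' missing or surplus cluster costs 99 and the cost vanishes exactly when
#' the clustering is 4 noise-free clusters of 180 frames.
#'
#' @param labels a `cluster_result` or integer label vector (noise = -1).
#' @param K target number of clusters (default 4).
#' @param alpha cluster-count deviation penalty weight (default 100).
#' @param beta cluster-size variance weight (default 0.01).
#' @param n_target expected per-cluster count (default 180, the per-class
#'   frame count of the reference dataset).
#' @return cost (numeric scalar, >= 0).
#' @export
cost_dbscan <- function(labels, K = 4, alpha = 100, beta = 0.01,
                        n_target = 180) {
  labels <- if (inherits(labels, "cluster_result")) labels$labels
            else as.integer(labels)
  .assert(length(labels) > 0, "labels must be non-empty")
  .assert(alpha > 0 && beta > 0 && beta < 1 && K >= 2,
          "require alpha > 0, 0 < beta < 1, K >= 2")
  n_out <- sum(labels == -1L)
  inside <- labels[labels != -1L]
  .assert(length(inside) > 0, "no non-noise points")
  sizes <- as.numeric(table(inside))
  n_in <- length(sizes)
  sigma <- mean((sizes - n_target)^2)
  n_out + (1 - beta) * (alpha * abs(n_in - K)) + beta * sigma
}

#' Describe one search-space parameter
#'
#' @param name parameter name.
#' @param lower,upper numeric bounds (inclusive).
#' @param log sample on a log scale.
#' @param choices character/numeric vector of discrete choices.
#' @return a parameter descriptor for [search_space()].
#' @export
param_numeric <- function(name, lower, upper, log = FALSE) {
  .assert(lower < upper, "bounds must be well-ordered")
  if (log) .assert(lower > 0, "log-scale bounds must be positive")
  list(name = name, type = "numeric", lower = lower, upper = upper, log = log)
}

#' @rdname param_numeric
#' @export
param_integer <- function(name, lower, upper, log = FALSE) {
  p <- param_numeric(name, lower, upper, log)
  p$type <- "integer"
  p
}

#' @rdname param_numeric
#' @export
param_choice <- function(name, choices) {
  .assert(length(choices) >= 1, "need at least one choice")
  list(name = name, type = "choice", choices = choices)
}

#' Hyperparameter search space
#'
#' @param ... parameter descriptors ([param_numeric()], [param_integer()],
#'   [param_choice()]).
#' @param budget number of cost evaluations (default 200).
#' @param seed integer seed.
#' @return an object of class `search_space`.
#' @export
search_space <- function(..., budget = 200, seed = 42) {
  params <- list(...)
  .assert(length(params) >= 1, "empty space")
  .assert(budget >= 1, "budget must be >= 1")
  names(params) <- vapply(params, `[[`, character(1), "name")
  structure(list(params = params, budget = as.integer(budget),
                 seed = as.integer(seed)),
            class = "search_space")
}

#' Default hyperparameter space for a clustering method
#'
#' The per-method spaces explored by the tuner: k-means (batch size, number
#' of restarts), agglomerative (linkage), spectral (affinity and its
#' parameter), DBSCAN (eps over a data-scaled log range, min_pts 3-20).
#'
#' @param method clustering method name.
#' @param x optional projection/matrix used to scale the DBSCAN eps range
#'   (from the 1st percentile to the median of sampled pairwise distances).
#' @param budget,seed passed to [search_space()].
#' @return a `search_space`.
#' @export
default_search_space <- function(method, x = NULL, budget = 200, seed = 42) {
  if (method == "kmeans") {
    search_space(param_integer("batch_size", 32, 1024, log = TRUE),
                 param_integer("n_init", 1, 10),
                 budget = budget, seed = seed)
  } else if (method == "agglomerative") {
    search_space(param_choice("linkage",
                              c("ward", "average", "complete", "single")),
                 budget = budget, seed = seed)
  } else if (method == "spectral") {
    search_space(param_choice("affinity", c("nearest_neighbors", "rbf")),
                 param_integer("n_neighbors", 5, 30),
                 param_numeric("gamma", 1e-3, 10, log = TRUE),
                 budget = budget, seed = seed)
  } else if (method == "dbscan") {
    lo <- 0.01; hi <- 10
    if (!is.null(x)) {
      X <- as_projection(x)$values
      n <- nrow(X)
      idx <- seq_len(min(n, 300))
      dd <- as.vector(dist(X[idx, , drop = FALSE]))
      lo <- max(quantile(dd, 0.01), 1e-6)
      hi <- max(quantile(dd, 0.5), lo * 10)
    }
    search_space(param_numeric("eps", lo, hi, log = TRUE),
                 param_integer("min_pts", 3, 20),
                 budget = budget, seed = seed)
  } else stop("unknown method: ", method, call. = FALSE)
}

# unit-cube point -> named parameter list
#' @noRd
.decode_point <- function(u, params) {
  out <- list()
  for (i in seq_along(params)) {
    p <- params[[i]]
    ui <- min(max(u[i], 0), 1)
    if (p$type == "choice") {
      j <- 1 + floor(ui * length(p$choices) * (1 - 1e-12))
      out[[p$name]] <- p$choices[[j]]
    } else {
      val <- if (isTRUE(p$log))
        exp(log(p$lower) + ui * (log(p$upper) - log(p$lower)))
      else p$lower + ui * (p$upper - p$lower)
      if (p$type == "integer") val <- as.integer(round(val))
      out[[p$name]] <- val
    }
  }
  out
}

# GP surrogate with squared-exponential kernel on the unit cube,
# expected-improvement acquisition over a random candidate set
#' @noRd
.gp_ei_propose <- function(U, y, n_cand, lengthscale = 0.2) {
  ys <- (y - mean(y)) / max(sd(y), 1e-12)
  k_fun <- function(A, B)
    exp(-.sqdist(A, B) / (2 * lengthscale^2))
  K <- k_fun(U, U) + diag(1e-6 + 1e-8, nrow(U))
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  cand <- matrix(runif(n_cand * ncol(U)), n_cand)
  Ks <- k_fun(cand, U)
  mu <- as.vector(Ks %*% alpha)
  v <- forwardsolve(t(L), t(Ks))
  s2 <- pmax(1 - colSums(v^2), 1e-12)
  s <- sqrt(s2)
  best <- min(ys)
  z <- (best - mu) / s
  ei <- s * (z * pnorm(z) + dnorm(z))
  cand[which.max(ei), ]
}

#' Search a hyperparameter space
#'
#' Minimizes a cost over a [search_space()] with either pure random search
#' or sequential model-based (Bayesian) optimization. The BO strategy
#' seeds a Latin hypercube design on the unit cube, fits a Gaussian-process
#' surrogate (squared-exponential kernel, fixed length-scale, small
#' nugget) to the standardized costs, and evaluates the
#' expected-improvement maximizer over a random candidate set at each
#' step. Both strategies are reproducible given the space seed.
#'
#' @param space a [search_space()].
#' @param evaluator function taking a named parameter list and returning a
#'   scalar cost (typically: cluster, label, evaluate, then
#'   [cost_partition()] or [cost_dbscan()]; see [clustering_evaluator()]).
#' @param strategy `"bo"` or `"random"`.
#' @return list with `best_params`, `best_cost`, `trace` (data frame of
#'   evaluated parameters and costs, one row per evaluation), `strategy`.
#' @export
search_hyperparams <- function(space, evaluator,
                               strategy = c("bo", "random")) {
  strategy <- match.arg(strategy)
  .assert(inherits(space, "search_space"), "space must be a search_space")
  params <- space$params
  dim <- length(params)
  budget <- space$budget
  withr::with_seed(space$seed, {
    if (strategy == "random") {
      U <- matrix(runif(budget * dim), budget)
    } else {
      n0 <- min(budget, max(4, 2 * dim))
      U <- lhs::randomLHS(n0, dim)
    }
    costs <- numeric(0)
    decoded <- list()
    i <- 1
    while (i <= budget) {
      if (i > nrow(U)) {                       # BO: propose next point
        u <- .gp_ei_propose(U, costs, n_cand = 500)
        U <- rbind(U, u)
      }
      decoded[[i]] <- .decode_point(U[i, ], params)
      costs[i] <- evaluator(decoded[[i]])
      i <- i + 1
    }
    best <- which.min(costs)
    trace <- cbind(do.call(rbind.data.frame,
                           lapply(decoded, as.data.frame)),
                   cost = costs)
    list(best_params = decoded[[best]], best_cost = costs[best],
         trace = trace, strategy = strategy)
  })
}

#' Build an Algorithm-style cost evaluator for a clustering method
#'
#' Wires a projection (and ground truth, for the partition branch) into a
#' function mapping a parameter point to its tuning cost: partition
#' methods run cluster -> automatic labeling -> macro recall/precision ->
#' [cost_partition()]; DBSCAN runs cluster -> [cost_dbscan()] (no labels
#' needed — the cost only inspects the partition shape).
#'
#' @param x projection (or matrix) to cluster.
#' @param method clustering method name.
#' @param truth ground-truth categories (required for partition methods).
#' @param K,alpha,beta,n_target DBSCAN cost parameters (see
#'   [cost_dbscan()]).
#' @param fixed named list of parameters held fixed (e.g. `n_clusters`).
#' @param seed seed forwarded to [cluster_features()].
#' @return function(params) -> cost.
#' @export
clustering_evaluator <- function(x, method, truth = NULL, K = 4,
                                 alpha = 100, beta = 0.01, n_target = 180,
                                 fixed = list(), seed = 42) {
  proj <- as_projection(x)
  if (method != "dbscan")
    .assert(!is.null(truth), "partition-method cost requires ground truth")
  function(params) {
    full <- modifyList(fixed, params)
    res <- tryCatch(
      cluster_features(proj, method = method, params = full, seed = seed),
      error = function(e) NULL)
    if (is.null(res)) return(1e6)              # infeasible point
    if (method == "dbscan")
      return(tryCatch(cost_dbscan(res, K = K, alpha = alpha, beta = beta,
                                  n_target = n_target),
                      error = function(e) 1e6))
    if (res$k_found != length(unique(as.character(truth)))) return(1e6)
    mapping <- tryCatch(greedy_label_map(cluster_contingency(res, truth)),
                        error = function(e) NULL)
    if (is.null(mapping)) return(1e6)
    mr <- classification_metrics(apply_label_map(res, mapping), truth)
    unname(cost_partition(mr$macro[["recall"]], mr$macro[["precision"]]))
  }
}
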