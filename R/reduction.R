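#' Principal component projection
#'
#' Projects an embedding matrix onto its top-`d` principal components:
#' the columns of the loading matrix are the leading eigenvectors of the
#' sample covariance of the column-centered data, ordered by descending
#' eigenvalue, and the projection is the centered data times the loadings.
#' Only centering is applied (no variance scaling). When `D > N` the
#' eigenproblem is solved through the Gram matrix, which yields the same
#' components without forming the `D x D` covariance.
#'
#' @param x a `frame_embedding` or numeric matrix (`N x D`).
#' @param d number of components, `1 <= d <= min(N - 1, D)`. Default 50,
#'   the dimensionality at which roughly 80% of the variance of CNN frame
#'   embeddings is typically retained.
#' @return an object of class `frame_projection` with `values` (`N x d`),
#'   `method = "pca"`, `d`, `params` (including per-component
#'   `explained_variance_ratio`), and `frame_ids`.
#' @export
pca_project <- function(x, d = 50) {
  emb <- as_embedding(x)
  X <- emb$values
  n <- nrow(X); p <- ncol(X)
  .assert(d >= 1 && d <= min(n - 1, p),
          "d must lie in [1, min(N - 1, D)]")
  Xc <- sweep(X, 2, colMeans(X))
  total_var <- sum(Xc^2) / (n - 1)
  .assert(total_var > 0, "zero-variance input")
  if (p <= n) {
    eg <- eigen(crossprod(Xc) / (n - 1), symmetric = TRUE)
    vals <- pmax(eg$values, 0)
    M <- eg$vectors[, seq_len(d), drop = FALSE]
  } else {                                   # Gram-matrix route for D > N
    eg <- eigen(tcrossprod(Xc), symmetric = TRUE)      # eigenvalues (n-1)*lambda
    vals <- pmax(eg$values, 0) / (n - 1)
    U <- eg$vectors[, seq_len(d), drop = FALSE]
    sc <- sqrt(pmax(eg$values[seq_len(d)], .Machine$double.eps))
    M <- crossprod(Xc, sweep(U, 2, sc, "/"))
  }
  # deterministic sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(M))) {
    piv <- which.max(abs(M[, j]))
    if (M[piv, j] < 0) M[, j] <- -M[, j]
  }
  Y <- Xc %*% M
  rownames(Y) <- emb$frame_ids
  structure(list(values = Y, method = "pca", d = as.integer(d),
                 params = list(explained_variance_ratio =
                                 vals[seq_len(d)] / total_var,
                               center = colMeans(X), rotation = M),
                 frame_ids = emb$frame_ids),
            class = "frame_projection")
}

#' Reduce an embedding to a low-dimensional space
#'
#' Uniform interface over the dimensionality-reduction methods of the
#' pipeline. `"none"` passes the embedding through unchanged; `"pca"`
#' delegates to [pca_project()]; `"tsne"` and `"umap"` wrap the
#' established Rtsne and uwot implementations (their objectives are not
#' re-derived here), run single-threaded and seeded so results are
#' reproducible.
#'
#' @param x a `frame_embedding` or numeric matrix.
#' @param method one of `"none"`, `"pca"`, `"tsne"`, `"umap"`.
#' @param params method parameters: `d` (output dimensionality; default 50
#'   for PCA, 2 for t-SNE/UMAP), t-SNE `perplexity` (default
#'   `min(30, floor((N - 1) / 3))`) and `eta` (learning rate, default 200),
#'   UMAP `n_neighbors` (default 15, capped at `N - 1`) and `min_dist`
#'   (default 0.1).
#' @param seed integer seed for the stochastic methods.
#' @return a `frame_projection` (values `N x d`, method, params, frame ids).
#' @export
reduce_embedding <- function(x, method = c("umap", "pca", "tsne", "none"),
                             params = list(), seed = 42) {
  method <- match.arg(method)
  emb <- as_embedding(x)
  X <- emb$values
  n <- nrow(X)
  if (method == "none") {
    return(structure(list(values = X, method = "none", d = ncol(X),
                          params = list(), frame_ids = emb$frame_ids),
                     class = "frame_projection"))
  }
  if (method == "pca") {
    d <- if (is.null(params$d)) min(50, n - 1, ncol(X)) else params$d
    return(pca_project(emb, d = d))
  }
  d <- if (is.null(params$d)) 2L else as.integer(params$d)
  .assert(d >= 2, "output dimensionality must be >= 2")
  if (method == "tsne") {
    perplexity <- if (is.null(params$perplexity))
      max(2, min(30, floor((n - 1) / 3))) else params$perplexity
    .assert(perplexity >= 2 && 3 * perplexity < n,
            "perplexity out of range for this N")
    eta <- if (is.null(params$eta)) 200 else params$eta
    Y <- withr::with_seed(seed,
      Rtsne::Rtsne(X, dims = d, perplexity = perplexity, eta = eta,
                   check_duplicates = FALSE, pca = ncol(X) > 50,
                   initial_dims = 50, num_threads = 1)$Y)
    used <- list(d = d, perplexity = perplexity, eta = eta,
                 implementation = paste0("Rtsne ",
                                         utils::packageVersion("Rtsne")))
  } else {
    n_neighbors <- if (is.null(params$n_neighbors)) 15 else params$n_neighbors
    n_neighbors <- max(2, min(n_neighbors, n - 1))
    min_dist <- if (is.null(params$min_dist)) 0.1 else params$min_dist
    .assert(min_dist >= 0, "min_dist must be >= 0")
    Y <- withr::with_seed(seed,
      uwot::umap(X, n_neighbors = n_neighbors, min_dist = min_dist,
                 n_components = d, n_threads = 1, n_sgd_threads = 0,
                 verbose = FALSE))
    used <- list(d = d, n_neighbors = n_neighbors, min_dist = min_dist,
                 implementation = paste0("uwot ",
                                         utils::packageVersion("uwot")))
  }
  .assert(all(is.finite(Y)), "reduction produced non-finite values")
  rownames(Y) <- emb$frame_ids
  structure(list(values = Y, method = method, d = d, params = used,
                 frame_ids = emb$frame_ids),
            class = "frame_projection")
}

#' @export
print.frame_projection <- function(x, ...) {
  cat("frame_projection:", nrow(x$values), "x", ncol(x$values),
      "| method:", x$method, "\n")
  invisible(x)
}

#' @noRd
as_projection <- function(x) {
  if (inherits(x, "frame_projection")) return(x)
  if (inherits(x, "frame_embedding"))
    return(structure(list(values = x$values, method = "none",
                          d = ncol(x$values), params = list(),
                          frame_ids = x$frame_ids),
                     class = "frame_projection"))
  .assert(is.matrix(x) && is.numeric(x), "x must be a numeric matrix")
  ids <- rownames(x)
  if (is.null(ids)) ids <- sprintf("row_%05d", seq_len(nrow(x)))
  structure(list(values = x, method = "none", d = ncol(x), params = list(),
                 frame_ids = ids),
            class = "frame_projection")
}
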