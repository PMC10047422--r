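#' @export
print.frameclust <- function(x, ...) {
  cat("Unsupervised frame-selection fit\n")
  cat("  frames    :", nrow(x$projection$values), "\n")
  cat("  embedding :", x$embedding$backend_tag, "\n")
  cat("  reduction :", x$projection$method, "(d =", x$projection$d, ")\n")
  cat("  clustering:", x$clusters$method, "| k_found =",
      x$clusters$k_found, "\n")
  if (!is.null(x$mapping))
    cat("  mapping   :", paste(names(x$mapping$map), "->", x$mapping$map,
                               collapse = ", "), "\n")
  if (!is.null(x$metrics))
    cat("  median recall:",
        sprintf("%.2f", x$metrics$median_iqr["median", "recall"]),
        "| accuracy:", sprintf("%.3f", x$metrics$accuracy), "\n")
  invisible(x)
}

#' Summarize a frame-selection fit
#'
#' @param object a `frameclust` fit.
#' @param ... unused.
#' @return an object of class `summary.frameclust` carrying per-class
#'   metrics, validity indices, cluster sizes and the label mapping.
#' @export
summary.frameclust <- function(object, ...) {
  structure(list(fit = object,
                 sizes = table(object$clusters$labels),
                 metrics = object$metrics,
                 auc = object$auc,
                 validity = object$validity),
            class = "summary.frameclust")
}

#' @export
print.summary.frameclust <- function(x, ...) {
  print(x$fit)
  cat("\ncluster sizes:\n")
  print(x$sizes)
  if (!is.null(x$validity)) {
    cat(sprintf("\naverage silhouette     : %.3f\n", x$validity$silhouette))
    cat(sprintf("Calinski-Harabasz index: %.2f\n",
                x$validity$calinski_harabasz))
  }
  if (!is.null(x$metrics)) {
    cat("\nclassification vs ground truth:\n")
    print(x$metrics)
  }
  if (!is.null(x$auc))
    cat("mean one-vs-rest AUC:", sprintf("%.3f", x$auc$mean_auc), "\n")
  invisible(x)
}

#' Fitted category (or cluster) assignments
#'
#' @param object a `frameclust` fit.
#' @param ... unused.
#' @return when a label mapping exists, the per-frame predicted category
#'   (with `"unassigned"` for density noise); otherwise the raw integer
#'   cluster labels.
#' @export
fitted.frameclust <- function(object, ...) {
  if (!is.null(object$predicted)) {
    setNames(object$predicted, object$clusters$frame_ids)
  } else {
    setNames(object$clusters$labels, object$clusters$frame_ids)
  }
}

#' Plot a frame-selection fit
#'
#' Scatter of the first two projection coordinates, colored by cluster;
#' when ground truth is present, point shape encodes the true category.
#'
#' @param x a `frameclust` fit.
#' @param ... forwarded to [graphics::plot()].
#' @export
plot.frameclust <- function(x, ...) {
  Y <- x$projection$values[, 1:2, drop = FALSE]
  labs <- x$clusters$labels
  cols <- hcl.colors(max(labs) + 2, "Dark 3")[labs + 2]
  pch <- if (!is.null(x$truth)) as.integer(factor(x$truth)) else 16
  plot(Y, col = cols, pch = pch,
       xlab = paste(x$projection$method, "1"),
       ylab = paste(x$projection$method, "2"), ...)
  if (!is.null(x$mapping))
    legend("topright", bty = "n",
           legend = paste(names(x$mapping$map), "->", x$mapping$map),
           col = hcl.colors(max(labs) + 2,
                            "Dark 3")[as.integer(names(x$mapping$map)) + 2],
           pch = 16)
  invisible(x)
}

#' Predict categories for new frames or embeddings
#'
#' Assigns new data to the nearest mapped cluster centroid in the
#' projection space. Available when the fit's reduction is `"none"` or
#' `"pca"` (the only reductions with an out-of-sample transform); UMAP and
#' t-SNE fits are transductive and cannot embed new points.
#'
#' @param object a `frameclust` fit with a label mapping.
#' @param newdata a `frame_set`, `frame_embedding` or numeric matrix.
#' @param ... unused.
#' @return character vector of predicted categories.
#' @export
predict.frameclust <- function(object, newdata, ...) {
  .assert(!is.null(object$mapping),
          "predict requires a fit with a label mapping (truth supplied)")
  .assert(object$projection$method %in% c("none", "pca"),
          "out-of-sample prediction needs a 'none' or 'pca' reduction")
  emb <- if (inherits(newdata, "frame_set"))
    extract_embeddings(newdata, backend = object$backend,
                       seed = .stage_seed(object$seed, "embed"))
  else as_embedding(if (inherits(newdata, "frame_embedding"))
    newdata$values else newdata)
  Y <- if (object$projection$method == "pca") {
    sweep(emb$values, 2, object$projection$params$center) %*%
      object$projection$params$rotation
  } else emb$values
  cl_ids <- as.integer(names(object$mapping$map))
  centroids <- t(vapply(cl_ids, function(j)
    colMeans(object$projection$values[object$clusters$labels == j, ,
                                      drop = FALSE]),
    numeric(ncol(object$projection$values))))
  nearest <- max.col(-.sqdist(Y, centroids))
  unname(object$mapping$map[nearest])
}
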