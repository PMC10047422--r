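#' Cluster-by-category contingency table
#'
#' Counts, for every cluster, how many of its frames carry each
#' ground-truth category — the intersection numbers on which automatic
#' cluster labeling operates. Density-noise points (label -1) are excluded
#' from the table and reported separately.
#'
#' @param clusters a `cluster_result` or integer label vector (noise = -1).
#' @param truth vector/factor of ground-truth categories, same length.
#' @return an object of class `cluster_contingency`: `counts` (`K x G`
#'   integer matrix, rows = clusters, columns = categories),
#'   `cluster_ids`, `category_ids`, `n_noise`.
#' @export
cluster_contingency <- function(clusters, truth) {
  labels <- if (inherits(clusters, "cluster_result")) clusters$labels
            else as.integer(clusters)
  .assert(length(labels) == length(truth),
          "clusters and truth must have equal length")
  .assert(length(labels) > 0, "empty input")
  cats <- if (is.factor(truth)) levels(truth) else {
    u <- unique(as.character(truth))
    known <- FRAME_CATEGORIES[FRAME_CATEGORIES %in% u]
    c(known, sort(setdiff(u, known)))
  }
  truth <- as.character(truth)
  keep <- labels != -1L
  cl_ids <- sort(unique(labels[keep]))
  counts <- matrix(0L, length(cl_ids), length(cats),
                   dimnames = list(cluster = as.character(cl_ids),
                                   category = cats))
  for (i in seq_along(cl_ids))
    for (j in seq_along(cats))
      counts[i, j] <- sum(labels == cl_ids[i] & truth == cats[j])
  structure(list(counts = counts, cluster_ids = cl_ids, category_ids = cats,
                 n_noise = sum(!keep)),
            class = "cluster_contingency")
}

#' @noRd
.as_contingency <- function(x) {
  if (inherits(x, "cluster_contingency")) return(x)
  .assert(is.matrix(x) && all(x >= 0), "expected a non-negative count matrix")
  cl <- rownames(x); if (is.null(cl)) cl <- as.character(seq_len(nrow(x)) - 1)
  ca <- colnames(x); if (is.null(ca)) ca <- paste0("cat", seq_len(ncol(x)))
  structure(list(counts = x, cluster_ids = cl, category_ids = ca,
                 n_noise = 0L),
            class = "cluster_contingency")
}

#' @noRd
.mapping_object <- function(tab, assign, mode) {
  map <- setNames(tab$category_ids[assign], as.character(tab$cluster_ids))
  total <- sum(tab$counts[cbind(seq_along(assign), assign)])
  structure(list(map = map, total_intersection = as.integer(total),
                 mode = mode, cluster_ids = tab$cluster_ids,
                 category_ids = tab$category_ids),
            class = "label_mapping")
}

#' Greedy automatic cluster labeling
#'
#' Assigns each cluster the category with which it shares the most frames,
#' iterating clusters in ascending cluster-id order; argmax ties break to
#' the lowest category index in the canonical order (I, B, S, U). The
#' greedy pass can map two clusters to the same category, which violates
#' the required bijection between clusters and categories; when that
#' happens the mapping is repaired by exhaustive maximization
#' ([optimal_label_map()]) and flagged with `mode = "optimal"`.
#'
#' @param tab a `cluster_contingency` (or plain count matrix) with as many
#'   clusters as categories.
#' @return an object of class `label_mapping`: `map` (named character
#'   vector, cluster id -> category), `total_intersection`, `mode`
#'   (`"greedy"` or `"optimal"` when repaired).
#' @export
greedy_label_map <- function(tab) {
  tab <- .as_contingency(tab)
  K <- nrow(tab$counts); G <- ncol(tab$counts)
  .assert(K == G,
          "cluster labeling requires as many clusters as categories")
  assign <- apply(tab$counts, 1, which.max)     # ties -> lowest column index
  if (anyDuplicated(assign)) {
    out <- optimal_label_map(tab)
    return(out)
  }
  .mapping_object(tab, assign, "greedy")
}

#' Optimal (exhaustive) cluster labeling
#'
#' Enumerates all `K!` bijections from clusters to categories and returns
#' one maximizing the total intersection; ties break to the
#' lexicographically first assignment. Serves both as the repair step for
#' greedy collisions and as an independent oracle for the greedy map.
#'
#' @param tab a `cluster_contingency` (or count matrix) with `K = G <= 10`.
#' @return a `label_mapping` with `mode = "optimal"`.
#' @export
optimal_label_map <- function(tab) {
  tab <- .as_contingency(tab)
  K <- nrow(tab$counts); G <- ncol(tab$counts)
  .assert(K == G, "requires as many clusters as categories")
  .assert(K <= 10, "exhaustive enumeration limited to K <= 10")
  perms <- .permutations(K)                     # lexicographic order
  best <- NULL; best_total <- -1
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    total <- sum(tab$counts[cbind(seq_len(K), p)])
    if (total > best_total) {                   # strict: keeps first tie
      best_total <- total
      best <- p
    }
  }
  .mapping_object(tab, best, "optimal")
}

# all permutations of 1..k in lexicographic order
#' @noRd
.permutations <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- .permutations(k - 1)
  out <- matrix(0L, 0, k)
  for (first in seq_len(k)) {
    rest <- setdiff(seq_len(k), first)
    out <- rbind(out, cbind(first, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

#' Apply a label mapping to cluster labels
#'
#' Translates integer cluster labels into category names; density-noise
#' points (-1) become `"unassigned"`, which downstream metrics count as a
#' missed detection for the true category and never as a true positive.
#'
#' @param clusters a `cluster_result` or integer label vector.
#' @param mapping a `label_mapping`.
#' @return character vector of categories (or `"unassigned"`).
#' @export
apply_label_map <- function(clusters, mapping) {
  labels <- if (inherits(clusters, "cluster_result")) clusters$labels
            else as.integer(clusters)
  out <- rep("unassigned", length(labels))
  idx <- match(as.character(labels), names(mapping$map))
  out[!is.na(idx)] <- mapping$map[idx[!is.na(idx)]]
  out
}

#' @export
print.label_mapping <- function(x, ...) {
  cat("label_mapping (", x$mode, "), total intersection ",
      x$total_intersection, "\n", sep = "")
  for (cl in names(x$map)) cat("  cluster", cl, "->", x$map[[cl]], "\n")
  invisible(x)
}
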