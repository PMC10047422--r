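#' Fit the unsupervised informative-frame-selection pipeline
#'
#' The one-stop fitting function: embeds frames (unless given a
#' precomputed embedding matrix), reduces the embedding to a
#' low-dimensional space, clusters it, and — when ground-truth categories
#' are available — aligns clusters to categories with the automatic
#' bijective labeling and evaluates the result as a classifier
#' (per-class precision/recall/F1, one-vs-rest AUC, validity indices).
#' Ground truth is never consulted before the labeling stage, so the fit
#' itself is fully unsupervised.
#'
#' Every randomized stage receives a sub-seed derived deterministically
#' from `seed` and the stage name, so refitting with the same inputs
#' reproduces the object exactly.
#'
#' @param x a `frame_set`, a `frame_embedding`, or a numeric matrix of
#'   per-frame features.
#' @param truth optional ground-truth categories (defaults to
#'   `x$labels` when `x` is a labeled frame set). Used only for labeling
#'   and evaluation.
#' @param backend embedding backend (see [extract_embeddings()]); ignored
#'   when `x` is already an embedding.
#' @param reduction reduction method (see [reduce_embedding()]).
#' @param reduction_params parameters for the reduction.
#' @param method clustering method (see [cluster_features()]).
#' @param method_params clustering parameters; `n_clusters` defaults to
#'   `k` for the partition methods.
#' @param k target number of clusters / categories (default 4: blurred,
#'   informative, specular, underexposed).
#' @param seed master seed.
#' @return an object of class `frameclust` with components `embedding`,
#'   `projection`, `clusters`, and (when truth is given) `mapping`,
#'   `predicted`, `metrics`, `scores`, `auc`; plus `validity` (average
#'   silhouette and Calinski-Harabasz index of the partition), `truth`,
#'   `k`, `seed` and `call`.
#' @seealso [summary.frameclust()], [plot.frameclust()],
#'   [predict.frameclust()], [run_pipeline()]
#' @export
#' @examples
#' frames <- generate_frame_set(n_per_class = 8, size = 64, seed = 3)
#' fit <- frameclust(frames, backend = "pixel-downsample",
#'                   reduction = "pca", method = "kmeans", seed = 3)
#' fit
frameclust <- function(x, truth = NULL,
                       backend = c("pixel-downsample", "cnn-vgg16-random"),
                       reduction = c("umap", "pca", "tsne", "none"),
                       reduction_params = list(),
                       method = c("agglomerative", "kmeans", "spectral",
                                  "dbscan"),
                       method_params = list(), k = 4, seed = 42) {
  backend <- match.arg(backend)
  reduction <- match.arg(reduction)
  method <- match.arg(method)
  cl <- match.call()

  if (inherits(x, "frame_set")) {
    if (is.null(truth)) truth <- x$labels
    embedding <- extract_embeddings(x, backend = backend,
                                    seed = .stage_seed(seed, "embed"))
  } else {
    embedding <- as_embedding(if (inherits(x, "frame_embedding")) x$values
                              else x)
  }
  projection <- reduce_embedding(embedding, method = reduction,
                                 params = reduction_params,
                                 seed = .stage_seed(seed, "reduce"))
  if (method != "dbscan" && is.null(method_params$n_clusters))
    method_params$n_clusters <- k
  clusters <- cluster_features(projection, method = method,
                               params = method_params,
                               seed = .stage_seed(seed, "cluster"))

  fit <- list(embedding = embedding, projection = projection,
              clusters = clusters, truth = truth, k = as.integer(k),
              seed = seed, backend = backend, call = cl)

  fit$validity <- tryCatch(
    list(silhouette = silhouette_score(projection, clusters)$average,
         calinski_harabasz = calinski_harabasz(projection, clusters)),
    error = function(e) NULL)

  if (!is.null(truth)) {
    tab <- cluster_contingency(clusters, truth)
    mapping <- tryCatch(greedy_label_map(tab), error = function(e) NULL)
    if (!is.null(mapping)) {
      predicted <- apply_label_map(clusters, mapping)
      fit$mapping <- mapping
      fit$predicted <- predicted
      fit$metrics <- classification_metrics(predicted, truth)
      fit$scores <- cluster_scores(projection, clusters, mapping)
      fit$auc <- tryCatch(roc_auc(fit$scores, truth),
                          error = function(e) NULL)
    } else {
      fit$mapping_error <- paste("cluster count", clusters$k_found,
                                 "does not match category count; no mapping")
    }
  }
  structure(fit, class = "frameclust")
}

#' Run the pipeline end-to-end with on-disk artifacts
#'
#' Orchestrates synthesize/load -> embed -> reduce -> (tune) -> cluster ->
#' label -> evaluate, writing every intermediate artifact (embeddings,
#' projection, cluster labels, mapping, metrics and a run report as JSON)
#' into `out_dir`. Fully reproducible given the config.
#'
#' @param config named list (or path to a JSON/YAML file) with elements:
#'   exactly one input source — `input_dir` (image folder),
#'   `embedding_file` (delimited matrix), or `synthetic`
#'   (`list(n_per_class =, size =)`) —, plus optional `backend`,
#'   `reduction`, `reduction_params`, `method`, `method_params`, `tune`
#'   (logical: tune `method`'s parameters before the final run), `budget`,
#'   `strategy`, `k`, and mandatory `seed`.
#' @param out_dir output directory for artifacts.
#' @return the run report (named list, also written to `report.json`),
#'   with the fitted `frameclust` object attached as attribute `"fit"`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  .assert(!is.null(config$seed), "config$seed is mandatory")
  sources <- c("input_dir", "embedding_file", "synthetic")
  have <- sources[sources %in% names(config)]
  .assert(length(have) == 1, "config must name exactly one input source")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  seed <- config$seed
  backend <- config$backend %||% "pixel-downsample"
  reduction <- config$reduction %||% "umap"
  method <- config$method %||% "agglomerative"
  k <- config$k %||% 4
  method_params <- as.list(config$method_params)
  stages <- list()

  frames <- NULL
  if (have == "synthetic") {
    sp <- config$synthetic
    frames <- generate_frame_set(sp$n_per_class %||% 30,
                                 size = sp$size %||% 128,
                                 seed = .stage_seed(seed, "synth"))
    write_frame_set(frames, file.path(out_dir, "frames"))
    stages$synth <- list(n = length(frames$images))
    x <- frames
  } else if (have == "input_dir") {
    x <- read_frame_set(config$input_dir)
    frames <- x
  } else {
    x <- read_embedding(config$embedding_file)
  }

  if (isTRUE(config$tune)) {
    emb <- if (inherits(x, "frame_set"))
      extract_embeddings(x, backend = backend,
                         seed = .stage_seed(seed, "embed"))
    else as_embedding(if (inherits(x, "frame_embedding")) x$values else x)
    proj <- reduce_embedding(emb, method = reduction,
                             params = as.list(config$reduction_params),
                             seed = .stage_seed(seed, "reduce"))
    space <- default_search_space(method, proj,
                                  budget = config$budget %||% 50,
                                  seed = .stage_seed(seed, "tune"))
    evaluator <- clustering_evaluator(
      proj, method, truth = if (inherits(x, "frame_set")) x$labels,
      K = k, n_target = nrow(proj$values) / k,
      fixed = method_params, seed = .stage_seed(seed, "cluster"))
    tuned <- search_hyperparams(space, evaluator,
                                strategy = config$strategy %||% "bo")
    method_params <- modifyList(method_params, tuned$best_params)
    utils::write.csv(tuned$trace, file.path(out_dir, "tuning_trace.csv"),
                     row.names = FALSE)
    stages$tune <- list(best_params = tuned$best_params,
                        best_cost = tuned$best_cost,
                        evaluations = nrow(tuned$trace))
  }

  fit <- frameclust(x, backend = backend, reduction = reduction,
                    reduction_params = as.list(config$reduction_params),
                    method = method, method_params = method_params,
                    k = k, seed = seed)

  write_embedding(fit$embedding, file.path(out_dir, "embeddings.tsv"))
  write_embedding(fit$projection, file.path(out_dir, "projection.tsv"))
  write_cluster_labels(fit$clusters, file.path(out_dir, "clusters.csv"))
  if (!is.null(fit$mapping))
    write_label_mapping(fit$mapping, file.path(out_dir, "mapping.json"))
  if (!is.null(fit$metrics)) {
    jsonlite::write_json(
      list(per_class = fit$metrics$per_class,
           macro = as.list(fit$metrics$macro),
           median = as.list(fit$metrics$median_iqr["median", ]),
           iqr = as.list(fit$metrics$median_iqr["iqr", ]),
           accuracy = fit$metrics$accuracy,
           mean_auc = if (!is.null(fit$auc)) fit$auc$mean_auc),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  report <- list(
    config = config,
    stages = c(stages, list(
      embed = list(backend = fit$embedding$backend_tag,
                   dim = ncol(fit$embedding$values)),
      reduce = list(method = fit$projection$method, d = fit$projection$d),
      cluster = list(method = fit$clusters$method,
                     params = fit$clusters$params,
                     k_found = fit$clusters$k_found,
                     n_noise = sum(fit$clusters$labels == -1)))),
    validity = fit$validity,
    mapping = if (!is.null(fit$mapping)) as.list(fit$mapping$map),
    metrics = if (!is.null(fit$metrics))
      list(macro = as.list(fit$metrics$macro),
           accuracy = fit$metrics$accuracy),
    files = list.files(out_dir, recursive = FALSE))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  attr(report, "fit") <- fit
  report
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
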