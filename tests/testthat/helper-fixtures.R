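# shared fixtures, built in code at test time

# small labeled frame set (cached per session; generation is deterministic)
small_frame_set <- local({
  cache <- NULL
  function(n_per_class = 6, size = 64, seed = 101) {
    key <- paste(n_per_class, size, seed)
    if (is.null(cache) || !identical(attr(cache, "key"), key)) {
      fs <- generate_frame_set(n_per_class, size = size, seed = seed)
      attr(fs, "key") <- key
      cache <<- fs
    }
    cache
  }
})

# well-separated blob embedding benchmark
blobs4 <- function(n_per_cluster = 40, dim = 10, separation = 20,
                   noise_sd = 1, seed = 7) {
  generate_blob_embeddings(blob_spec(4, n_per_cluster, dim,
                                     separation = separation,
                                     noise_sd = noise_sd, seed = seed))
}

# random contingency table with controllable diagonal dominance
random_table <- function(k = 4, max_count = 200) {
  matrix(sample.int(max_count, k * k, replace = TRUE), k, k)
}

# agreement between two labelings after the optimal bijection
mapped_agreement <- function(cl, truth) {
  tab <- cluster_contingency(cl, truth)
  if (nrow(tab$counts) != ncol(tab$counts)) return(0)
  optimal_label_map(tab)$total_intersection
}
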