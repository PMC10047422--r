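test_that("confusion-based metrics match the defining formulas", {
  # a category with TP = 9, FP = 1, FN = 3
  truth <- c(rep("A", 12), rep("B", 10))
  pred <- c(rep("A", 9), rep("B", 3), "A", rep("B", 9))
  mr <- classification_metrics(pred, truth)
  a <- mr$per_class[mr$per_class$category == "A", ]
  expect_equal(a$tp, 9); expect_equal(a$fp, 1); expect_equal(a$fn, 3)
  expect_equal(a$precision, 0.9)
  expect_equal(a$recall, 0.75)
  expect_equal(a$f1, 18 / 22)
})

test_that("perfect predictions score 1 and zero-denominators score 0", {
  truth <- rep(c("I", "B", "S", "U"), each = 5)
  mr <- classification_metrics(truth, truth)
  expect_true(all(mr$per_class[c("precision", "recall", "f1")] == 1))
  expect_equal(mr$accuracy, 1)
  # category never predicted and never true positive
  pred <- rep("B", 20)
  mr0 <- classification_metrics(pred, truth)
  i_row <- mr0$per_class[mr0$per_class$category == "I", ]
  expect_equal(i_row$precision, 0)
  expect_equal(i_row$recall, 0)
  expect_equal(i_row$f1, 0)
})

test_that("F1 is the harmonic mean of precision and recall everywhere", {
  set.seed(21)
  for (rep in 1:20) {
    truth <- sample(c("I", "B", "S", "U"), 60, replace = TRUE)
    pred <- sample(c("I", "B", "S", "U", "unassigned"), 60, replace = TRUE)
    mr <- classification_metrics(pred, truth)
    with(mr$per_class, {
      h <- ifelse(precision + recall > 0,
                  2 * precision * recall / (precision + recall), 0)
      expect_equal(f1, h, tolerance = 1e-12)
    })
  }
})

test_that("unassigned predictions count as misses, never true positives", {
  truth <- c("I", "I", "B", "B")
  pred <- c("I", "unassigned", "B", "unassigned")
  mr <- classification_metrics(pred, truth)
  expect_equal(mr$per_class$tp, c(1, 1))
  expect_equal(mr$per_class$fn, c(1, 1))
  expect_equal(mr$per_class$fp, c(0, 0))
  expect_equal(mr$accuracy, 0.5)
})

test_that("median and Tukey-hinge IQR reproduce the printed summaries", {
  expect_equal(median_and_iqr(c(0.83, 0.91, 0.62, 0.85)),
               c(median = 0.84, iqr = 0.155), tolerance = 1e-12)
  expect_equal(round(median_and_iqr(c(0.83, 0.91, 0.62, 0.85)), 2),
               c(median = 0.84, iqr = 0.16))
  expect_equal(round(median_and_iqr(c(0.98, 0.95, 0.86, 0.93)), 2),
               c(median = 0.94, iqr = 0.07))
  expect_equal(median_and_iqr(c(1, 2, 3, 4, 5)),
               c(median = 3, iqr = 2))
  expect_error(median_and_iqr(0.5), "two values")
})

test_that("rank-based AUC agrees with pair enumeration and handles ties", {
  sc <- cbind("1" = c(0.1, 0.4, 0.35, 0.8))
  expect_equal(roc_auc(sc, c(0, 0, 1, 1))$per_class[["1"]], 0.75)
  # perfectly separating scores
  sc2 <- cbind(A = c(1, 2, 9, 10))
  expect_equal(roc_auc(sc2, c("B", "B", "A", "A"))$per_class[["A"]], 1.0)
  # constant scores give 0.5 under midranks
  sc3 <- cbind(A = rep(1, 6))
  expect_equal(roc_auc(sc3, rep(c("A", "B"), 3))$per_class[["A"]], 0.5)
})

test_that("AUC matches an independent implementation on random scores", {
  skip_if_not_installed("pROC")
  set.seed(31)
  for (rep in 1:10) {
    truth <- sample(c("A", "B"), 40, replace = TRUE)
    sc <- cbind(A = rnorm(40), B = rnorm(40))
    ours <- roc_auc(sc, truth)$per_class[["A"]]
    ref <- as.numeric(pROC::auc(pROC::roc(truth == "A", sc[, "A"],
                                          quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("silhouette matches the hand-computed toy example", {
  Y <- matrix(c(0, 1, 10, 11), ncol = 1)
  lab <- c(0, 0, 1, 1)
  s <- silhouette_score(Y, lab)
  expect_equal(s$per_point[1], (10.5 - 1) / 10.5, tolerance = 1e-12)
  # two identical co-located clusters: a -> b as clusters grow, average ~ 0
  set.seed(5)
  block <- matrix(rnorm(60), 30, 2)
  Y2 <- rbind(block, block)
  expect_lt(abs(silhouette_score(Y2, rep(c(0, 1), each = 30))$average),
            0.05)
  expect_error(silhouette_score(Y, c(0, 0, 0, 0)), "two clusters")
})

test_that("silhouette and CH match brute-force oracles on random instances", {
  brute_sil <- function(Y, lab) {
    n <- nrow(Y)
    s <- numeric(n)
    for (i in seq_len(n)) {
      di <- sqrt(colSums((t(Y) - Y[i, ])^2))
      own <- lab == lab[i]
      if (sum(own) == 1) { s[i] <- 0; next }
      a <- mean(di[own & seq_len(n) != i])
      b <- min(vapply(setdiff(unique(lab), lab[i]),
                      function(g) mean(di[lab == g]), numeric(1)))
      s[i] <- (b - a) / max(a, b)
    }
    mean(s)
  }
  brute_ch <- function(Y, lab) {
    grand <- colMeans(Y)
    bg <- 0; wg <- 0
    for (g in unique(lab)) {
      P <- Y[lab == g, , drop = FALSE]
      ctr <- colMeans(P)
      bg <- bg + nrow(P) * sum((ctr - grand)^2)
      wg <- wg + sum(t(t(P) - ctr)^2)
    }
    (bg / (length(unique(lab)) - 1)) / (wg / (nrow(Y) - length(unique(lab))))
  }
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(10:30, 1)
    Y <- matrix(rnorm(n * 3), n, 3)
    lab <- sample(0:2, n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(silhouette_score(Y, lab)$average, brute_sil(Y, lab),
                 tolerance = 1e-9)
    expect_equal(calinski_harabasz(Y, lab), brute_ch(Y, lab),
                 tolerance = 1e-9)
  }
})

test_that("silhouette agrees with the cluster package", {
  skip_if_not_installed("cluster")
  set.seed(43)
  Y <- matrix(rnorm(25 * 2), 25, 2)
  lab <- sample(1:3, 25, replace = TRUE)
  ours <- silhouette_score(Y, lab)$average
  ref <- mean(cluster::silhouette(lab, dist(Y))[, "sil_width"])
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("CH matches the hand-computed toy value of 200", {
  Y <- matrix(c(0, 1, 10, 11), ncol = 1)
  expect_equal(calinski_harabasz(Y, c(0, 0, 1, 1)), 200)
  expect_error(calinski_harabasz(Y, c(0, 1, 2, 3)), "K < N")
  # coincident points within each cluster: WGSS = 0
  Y0 <- matrix(c(0, 0, 5, 5), ncol = 1)
  expect_warning(ch0 <- calinski_harabasz(Y0, c(0, 0, 1, 1)), "zero")
  expect_true(is.infinite(ch0))
})

test_that("doubling blob separation strictly increases CH", {
  for (seed in 1:3) {
    ch <- vapply(c(10, 20), function(sep) {
      out <- generate_blob_embeddings(blob_spec(3, 30, 5, separation = sep,
                                                noise_sd = 1, seed = seed))
      calinski_harabasz(out$embedding$values, out$labels)
    }, numeric(1))
    expect_gt(ch[2], ch[1])
  }
})

test_that("CH sweep recovers the true blob count", {
  out4 <- blobs4(n_per_cluster = 45, dim = 10, separation = 20)
  det4 <- determine_cluster_number(out4$embedding, 2:6, seed = 1)
  expect_equal(det4$chosen_k, 4L)
  out3 <- generate_blob_embeddings(blob_spec(3, 45, 10, separation = 20,
                                             noise_sd = 1, seed = 3))
  det3 <- determine_cluster_number(out3$embedding, 2:6, seed = 1)
  expect_equal(det3$chosen_k, 3L)
  det_fixed <- determine_cluster_number(out4$embedding, c(2, 2), seed = 1)
  expect_equal(det_fixed$chosen_k, 2L)
})

test_that("exact Wilcoxon p-values match published-table comparisons", {
  ours <- c(0.98, 0.94, 0.89, 0.97)
  expect_equal(wilcoxon_exact(ours, c(0.83, 0.91, 0.62, 0.85))$p_value,
               0.125)
  expect_equal(wilcoxon_exact(ours, c(0.96, 0.97, 0.88, 0.93))$p_value,
               0.625)
  expect_equal(wilcoxon_exact(ours, c(0.94, 1.00, 0.91, 0.94))$p_value,
               1.000)
  ident <- wilcoxon_exact(ours, ours)
  expect_equal(ident$p_value, 1.0)
  expect_true(ident$all_zero)
})

test_that("exact Wilcoxon agrees with stats::wilcox.test for untied data", {
  set.seed(51)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    a <- rnorm(n); b <- rnorm(n)
    ref <- suppressWarnings(wilcox.test(a, b, paired = TRUE,
                                        exact = TRUE))$p.value
    expect_equal(wilcoxon_exact(a, b)$p_value, ref, tolerance = 1e-12)
  }
})

test_that("cluster scores rank the mapped cluster's members highest", {
  out <- blobs4(n_per_cluster = 30, dim = 6, separation = 20)
  truth <- c("I", "B", "S", "U")[out$labels]
  cl <- cluster_features(out$embedding, "kmeans", list(n_clusters = 4),
                         seed = 8)
  m <- greedy_label_map(cluster_contingency(cl, truth))
  sc <- cluster_scores(out$embedding, cl, m)
  expect_equal(sort(colnames(sc)), sort(c("I", "B", "S", "U")))
  auc <- roc_auc(sc, truth)
  expect_gt(auc$mean_auc, 0.99)
})
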