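test_that("partition cost matches hand evaluations of the formula", {
  expect_equal(cost_partition(1.0, 1.0), 0.0)
  expect_equal(cost_partition(0.9, 0.8), 0.11)
  expect_equal(cost_partition(0.5, 0.5), 0.5)
  expect_error(cost_partition(1.2, 0.5))
})

test_that("partition cost is zero only at perfect balanced performance", {
  set.seed(1)
  for (i in 1:200) {
    sr <- runif(1); sp <- runif(1)
    co <- cost_partition(sr, sp)
    expect_gte(co, 0)
    if (co == 0) expect_true(sr == 1 && sp == 1)
  }
  # monotone non-increasing in recall at fixed |recall - precision|
  gap <- 0.05
  costs <- vapply(seq(0.05, 0.95, by = 0.05),
                  function(sr) cost_partition(sr, sr - gap), numeric(1))
  expect_true(all(diff(costs) < 0))
})

test_that("density cost matches hand evaluations of the formula", {
  # 4 clusters x 180 points, no noise: every term vanishes
  perfect <- rep(0:3, each = 180)
  expect_equal(cost_dbscan(perfect), 0.0)
  # 5 extra noise points cost exactly 5
  expect_equal(cost_dbscan(c(perfect, rep(-1, 5))), 5.0)
  # 3 clusters sized (180, 180, 175): 0.99 * 100 + 0.01 * 25/3
  three <- rep(0:2, times = c(180, 180, 175))
  expect_equal(cost_dbscan(three), 0.99 * 100 + 0.01 * 25 / 3,
               tolerance = 1e-12)
})

test_that("density cost is invariant to relabeling and increasing in noise", {
  labels <- rep(c(0, 1, 2, 3), times = c(170, 180, 185, 180))
  relabeled <- c(7, 2, 9, 5)[labels + 1]
  expect_equal(cost_dbscan(labels), cost_dbscan(relabeled))
  with_noise <- function(k) c(labels, rep(-1, k))
  costs <- vapply(0:5, function(k) cost_dbscan(with_noise(k)), numeric(1))
  expect_true(all(diff(costs) > 0))
  expect_error(cost_dbscan(rep(-1, 10)), "non-noise")
})

test_that("random search on a constant surface returns the first point", {
  sp <- search_space(param_numeric("x", 0, 1), budget = 10, seed = 1)
  res <- search_hyperparams(sp, function(p) 1.0, strategy = "random")
  expect_equal(nrow(res$trace), 10)
  expect_equal(res$best_cost, 1.0)
  expect_equal(res$best_params, as.list(res$trace[1, "x", drop = FALSE]))
})

test_that("exhaustive random search finds the minimum of a quadratic grid", {
  sp <- search_space(param_integer("x", 1, 20), budget = 200, seed = 2)
  res <- search_hyperparams(sp, function(p) (p$x - 13)^2, strategy = "random")
  expect_equal(res$best_params$x, 13L)       # 200 draws exhaust 20 cells
  expect_equal(res$best_cost, 0)
})

test_that("search is bit-reproducible under the space seed", {
  sp <- search_space(param_numeric("x", 0, 1), param_choice("m", c("a", "b")),
                     budget = 15, seed = 9)
  f <- function(p) p$x + (p$m == "a") * 0.1
  r1 <- search_hyperparams(sp, f, strategy = "random")
  r2 <- search_hyperparams(sp, f, strategy = "random")
  expect_identical(r1$trace, r2$trace)
  b1 <- search_hyperparams(sp, f, strategy = "bo")
  b2 <- search_hyperparams(sp, f, strategy = "bo")
  expect_identical(b1$trace, b2$trace)
})

test_that("BO concentrates evaluations near the optimum of a smooth cost", {
  sp <- search_space(param_numeric("x", 0, 1), budget = 30, seed = 4)
  f <- function(p) (p$x - 0.7)^2
  bo <- search_hyperparams(sp, f, strategy = "bo")
  expect_lt(bo$best_cost, 0.01)
  expect_equal(nrow(bo$trace), 30)
})

test_that("tuning a dbscan space on blobs drives the cluster count to K", {
  out <- blobs4(n_per_cluster = 45, dim = 10, separation = 20, noise_sd = 1)
  proj <- reduce_embedding(out$embedding, "none")
  space <- default_search_space("dbscan", proj, budget = 40, seed = 5)
  ev <- clustering_evaluator(proj, "dbscan", K = 4, n_target = 45)
  res <- search_hyperparams(space, ev, strategy = "bo")
  best <- cluster_features(proj, "dbscan", res$best_params)
  expect_equal(best$k_found, 4L)
  # and BO and random search agree on the attainable optimum here
  res_rs <- search_hyperparams(space, ev, strategy = "random")
  expect_lt(abs(res$best_cost - res_rs$best_cost), 0.003)
})

test_that("partition-branch evaluator rewards parameter choices that recover truth", {
  out <- blobs4(n_per_cluster = 30, dim = 8, separation = 20, noise_sd = 1)
  truth <- c("I", "B", "S", "U")[out$labels]
  ev <- clustering_evaluator(out$embedding, "agglomerative", truth = truth,
                             fixed = list(n_clusters = 4))
  expect_equal(ev(list(linkage = "ward")), 0)   # perfect recovery
  space <- default_search_space("agglomerative", budget = 8, seed = 6)
  res <- search_hyperparams(space, ev, strategy = "random")
  expect_equal(res$best_cost, 0)
})

test_that("space constructors validate their arguments", {
  expect_error(param_numeric("x", 2, 1), "well-ordered")
  expect_error(param_numeric("x", -1, 1, log = TRUE), "positive")
  expect_error(search_space(budget = 5), "empty")
  expect_error(search_space(param_numeric("x", 0, 1), budget = 0), "budget")
})
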