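test_that("every category obeys its measurable pixel criterion", {
  for (seed in c(1, 2, 3)) {
    b <- frame_stats(generate_frame(frame_spec("B", 96, 96, seed = seed)))
    i <- frame_stats(generate_frame(frame_spec("I", 96, 96, seed = seed)))
    s <- frame_stats(generate_frame(frame_spec("S", 96, 96, seed = seed)))
    u <- frame_stats(generate_frame(frame_spec("U", 96, 96, seed = seed)))
    expect_lte(i$bright_fraction, 0.10)     # small reflections only
    expect_gte(s$bright_fraction, 0.50)     # blobs cover at least half
    expect_gte(u$dark_fraction, 0.90)       # underexposed
    expect_lt(b$bright_fraction, 0.10)
  }
})

test_that("explicit spec fractions are honored", {
  s <- generate_frame(frame_spec("S", 128, 128, reflection_fraction = 0.6,
                                 seed = 1))
  expect_gte(frame_stats(s)$bright_fraction, 0.50)
  u <- generate_frame(frame_spec("U", 128, 128, dark_fraction = 0.95,
                                 seed = 1))
  expect_gte(frame_stats(u)$dark_fraction, 0.90)
})

test_that("frame generation is bit-identical under the same spec", {
  a <- generate_frame(frame_spec("S", 64, 64, seed = 9))
  b <- generate_frame(frame_spec("S", 64, 64, seed = 9))
  expect_identical(a, b)
  expect_false(identical(a, generate_frame(frame_spec("S", 64, 64,
                                                      seed = 10))))
})

test_that("spec invariants are enforced", {
  expect_error(frame_spec("X", 64, 64), "category")
  expect_error(frame_spec("I", 64, 64, reflection_fraction = 0.5), "10%")
  expect_error(frame_spec("S", 64, 64, reflection_fraction = 0.2), "half")
  expect_error(frame_spec("U", 64, 64, dark_fraction = 0.5), "90%")
  expect_error(frame_spec("I", 0, 64), "pixels")
})

test_that("sharp informative frames beat blurred ones on Laplacian variance", {
  for (seed in 1:5) {
    lv_i <- frame_stats(generate_frame(frame_spec("I", 96, 96,
                                                  seed = seed)))$laplacian_variance
    lv_b <- frame_stats(generate_frame(frame_spec("B", 96, 96,
                                                  seed = seed)))$laplacian_variance
    expect_gt(lv_i, lv_b)
  }
})

test_that("frame sets have balanced labels and deterministic shuffling", {
  fs <- generate_frame_set(5, size = 32, seed = 4)
  expect_length(fs$images, 20)
  expect_equal(unname(table(fs$labels)), rep(5L, 4), ignore_attr = TRUE)
  fs1 <- generate_frame_set(1, size = 32, seed = 4)
  expect_length(fs1$images, 4)
  expect_setequal(as.character(fs1$labels), c("I", "B", "S", "U"))
  fs_again <- generate_frame_set(5, size = 32, seed = 4)
  expect_identical(fs$images, fs_again$images)
  expect_identical(fs$labels, fs_again$labels)
  expect_error(generate_frame_set(0), ">= 1")
})

test_that("blob generator places clusters at the requested separation", {
  out <- blobs4(n_per_cluster = 180, dim = 50, separation = 20, noise_sd = 1)
  X <- out$embedding$values
  expect_equal(dim(X), c(720, 50))
  # per-cluster sample means within 3 * noise_sd / sqrt(n) of the centers
  for (k in 1:4) {
    ctr <- numeric(50)
    ctr[k] <- 20 / sqrt(2)
    mu <- colMeans(X[out$labels == k, ])
    expect_lt(max(abs(mu - ctr)), 3 * 1 / sqrt(180) * 3)
  }
  # pairwise center distances all equal `separation`
  centers <- t(sapply(1:4, function(k) colMeans(X[out$labels == k, ])))
  d <- dist(centers)
  expect_true(all(abs(d - 20) < 0.5))
})

test_that("blob embeddings are deterministic and degenerate at zero separation", {
  s <- blob_spec(3, 30, 5, separation = 0, noise_sd = 1, seed = 2)
  a <- generate_blob_embeddings(s)
  b <- generate_blob_embeddings(s)
  expect_identical(a$embedding$values, b$embedding$values)
  sil <- silhouette_score(a$embedding$values, a$labels)
  expect_lt(abs(sil$average), 0.1)          # clusters indistinguishable
})

test_that("within-cluster covariance converges to noise_sd^2 * I", {
  out <- generate_blob_embeddings(blob_spec(2, 2000, 4, separation = 30,
                                            noise_sd = 2, seed = 5))
  X <- out$embedding$values[out$labels == 1, ]
  S <- cov(X)
  expect_lt(max(abs(diag(S) - 4)) / 4, 0.10)
  off <- S[upper.tri(S)]
  expect_lt(max(abs(off)) / 4, 0.10)
})

test_that("blob spec validates its arguments", {
  expect_error(blob_spec(1, 10, 5), "n_clusters")
  expect_error(blob_spec(3, 10, 5, noise_sd = 0), "noise_sd")
  expect_error(blob_spec(3, 10, 2, separation = 10), "equidistant")
})
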