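test_that("k-means recovers trivial and brute-force-verified partitions", {
  # perfectly separated duplicates
  r <- kmeans_fit(c(0, 0, 10, 10), 2, seed = 1)
  expect_equal(sort(c(r$centers)), c(0, 10))
  expect_equal(r$total_sse, 0)
  expect_true(same_partition(r$labels, c(0, 0, 1, 1)))

  # brute force over all 2-partitions of {0, 2, 10, 12}: optimum SSE = 4
  x <- c(0, 2, 10, 12)
  expect_equal(brute_kmeans_sse(x, 2), 4)
  r2 <- kmeans_fit(x, 2, seed = 1)
  expect_equal(r2$total_sse, 4)
  expect_true(same_partition(r2$labels, c(0, 0, 1, 1)))

  # K = 1: centroid at the mean, SSE = n * population variance
  set.seed(5); y <- rnorm(50)
  r3 <- kmeans_fit(y, 1, seed = 9)
  expect_equal(c(r3$centers), mean(y))
  expect_equal(r3$total_sse, sum((y - mean(y))^2))
})

test_that("cluster_result invariants hold at convergence", {
  set.seed(2)
  blobs <- make_blobs(rbind(c(0, 0), c(1, 0), c(0.5, 1)), 40, 0.05, seed = 2)
  r <- kmeans_fit(blobs$X, 3, seed = 4)
  expect_equal(r$total_sse, sum(r$sse_per_cluster))
  expect_true(all(tabulate(r$labels + 1L, 3) >= 1))
  # each observation sits with its nearest centroid
  d2 <- sapply(1:3, function(k)
    rowSums(sweep(blobs$X, 2, r$centers[k, ])^2))
  expect_equal(max.col(-d2) - 1L, r$labels)
  # Lloyd monotonicity, asserted per iteration
  expect_true(all(diff(r$sse_history) <= 1e-9))
})

test_that("k-means is deterministic per seed and permutation invariant", {
  blobs <- make_blobs(rbind(c(0, 0), c(3, 3)), 30, 0.3, seed = 7)
  a <- kmeans_fit(blobs$X, 2, seed = 123)
  b <- kmeans_fit(blobs$X, 2, seed = 123)
  expect_identical(a$labels, b$labels)
  expect_identical(a$centers, b$centers)

  set.seed(99); perm <- sample(nrow(blobs$X))
  p <- kmeans_fit(blobs$X[perm, ], 2, seed = 123)
  expect_true(same_partition(p$labels, a$labels[perm]))
  expect_equal(p$total_sse, a$total_sse)
})

test_that("empty clusters are repaired so every cluster has a member", {
  # more clusters than distinct points forces repair
  X <- matrix(c(0, 0, 0, 0, 5, 5), ncol = 1)
  r <- kmeans_fit(X, 4, seed = 3)
  expect_true(all(tabulate(r$labels + 1L, 4) >= 1))
  expect_gt(r$repairs, 0)
})

test_that("input contracts are enforced", {
  expect_error(kmeans_fit(c(1, 2), 3), "at least K")
  expect_error(kmeans_fit(c(1, NA, 3), 2), "finite")
  expect_error(kmeans_fit(matrix(1:4, 2), 0), "K must be")
  expect_error(bisecting_kmeans(c(1, Inf), 2), "finite")
})

test_that("bisecting k-means first split equals plain 2-means under the same seeding", {
  blobs <- make_blobs(rbind(c(0, 0), c(2, 1)), 25, 0.2, seed = 13)
  bi <- bisecting_kmeans(blobs$X, 2, seed = 77, n_trial_bisections = 1)
  km <- kmeans_fit(blobs$X, 2, seed = firemapr:::bisect_seed(77, 1, 1))
  expect_true(same_partition(bi$labels, km$labels))
  expect_equal(bi$total_sse, km$total_sse, tolerance = 1e-12)
})

test_that("bisecting k-means matches brute force on separated 1-D triples", {
  x <- c(0, 1, 10, 11, 20, 21)
  expect_equal(brute_kmeans_sse(x, 3), 1.5)
  r <- bisecting_kmeans(x, 3, seed = 1)
  expect_equal(r$total_sse, 1.5)
  expect_true(same_partition(r$labels, c(0, 0, 1, 1, 2, 2)))
})

test_that("bisecting k-means attains the exhaustive optimum on small separated instances", {
  cases <- list(
    list(centers = rbind(0, 1), n = 5, sigma = 0.05, K = 2, d = 1),
    list(centers = rbind(0, 1, 2.2), n = 4, sigma = 0.04, K = 3, d = 1),
    list(centers = rbind(c(0, 0), c(1, 1)), n = 6, sigma = 0.03, K = 2, d = 2),
    list(centers = rbind(c(0, 0), c(1, 0), c(0, 1.3)), n = 4, sigma = 0.02,
         K = 3, d = 2))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    blobs <- make_blobs(cs$centers, cs$n, cs$sigma, seed = 100 + i)
    opt <- brute_kmeans_sse(blobs$X, cs$K)
    r <- bisecting_kmeans(blobs$X, cs$K, seed = i)
    expect_equal(r$total_sse, opt, tolerance = 1e-9,
                 info = sprintf("case %d", i))
  }
})

test_that("bisecting SSE is non-increasing in the cluster count", {
  blobs <- make_blobs(rbind(c(0, 0), c(1, 0), c(2, 1), c(0, 2)), 15, 0.2,
                      seed = 21)
  r <- bisecting_kmeans(blobs$X, 6, seed = 5)
  expect_equal(length(r$sse_history), 6)
  expect_true(all(diff(r$sse_history) <= 1e-9))
})

test_that("two well-separated blobs are recovered without error", {
  blobs <- make_blobs(rbind(c(0, 0), c(1, 0)), 100, 0.01, seed = 31)
  r <- bisecting_kmeans(blobs$X, 2, seed = 8)
  expect_true(same_partition(r$labels, blobs$labels))
})

test_that("degenerate inputs still yield K non-empty clusters", {
  # singletons: every split ends in size-1 clusters, K is still reached
  r <- bisecting_kmeans(matrix(c(0, 5, 9), ncol = 1), 3, seed = 1)
  expect_equal(r$K, 3)
  expect_equal(r$total_sse, 0)
  # identical points: empty-cluster repair carries the bisection through
  r2 <- bisecting_kmeans(matrix(c(0, 0, 0, 0), ncol = 1), 3, seed = 1)
  expect_equal(r2$K, 3)
  expect_true(all(tabulate(r2$labels + 1L, 3) >= 1))
  expect_equal(r2$total_sse, 0)
})

test_that("partitions agree with an independent k-means on separated data", {
  blobs <- make_blobs(rbind(c(0, 0), c(2, 2), c(4, 0)), 30, 0.1, seed = 41)
  ours <- kmeans_fit(blobs$X, 3, seed = 11)
  ref <- stats::kmeans(blobs$X, centers = 3, nstart = 10)
  expect_true(same_partition(ours$labels, ref$cluster))
  expect_equal(ours$total_sse, ref$tot.withinss, tolerance = 1e-9)
})
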