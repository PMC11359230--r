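# Independent oracles used to freeze expected values.

# Exact k-means optimum by exhaustive enumeration of all K^n assignments.
# Feasible for n <= 12, K <= 3. Empty clusters contribute nothing, so the
# result is the optimum over partitions into at most K clusters, which for
# separated data equals the K-cluster optimum.
brute_kmeans_sse <- function(X, K) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  n <- nrow(X)
  stopifnot(K^n <= 2^21)
  idx <- 0:(K^n - 1)
  digs <- matrix(0L, length(idx), n)
  for (j in seq_len(n)) digs[, j] <- as.integer((idx %/% K^(j - 1)) %% K)
  total <- numeric(length(idx))
  for (k in 0:(K - 1)) {
    mem <- digs == k
    cnt <- rowSums(mem)
    for (d in seq_len(ncol(X))) {
      s <- as.numeric(mem %*% X[, d])
      q <- as.numeric(mem %*% (X[, d]^2))
      total <- total + q - ifelse(cnt > 0, s^2 / cnt, 0)
    }
  }
  min(total)
}

# well-separated Gaussian blobs with ground-truth labels
make_blobs <- function(centers, n_per, sigma, seed) {
  centers <- as.matrix(centers)
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    matrix(rnorm(n_per * ncol(centers), sd = sigma), n_per) +
      matrix(centers[i, ], n_per, ncol(centers), byrow = TRUE)))
  list(X = X, labels = rep(seq_len(nrow(centers)) - 1L, each = n_per))
}
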