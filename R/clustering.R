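# Self-contained Lloyd k-means with k-means++ seeding, and bisecting k-means
# (repeatedly split the cluster with the highest SSE via 2-means). Squared
# Euclidean metric on unscaled features: the two index differences fed to the
# fire-mapping stage share units and range, so no standardization is applied.
#
# Determinism and permutation invariance: observations are put into a
# canonical (lexicographic) order before seeding, so for a fixed seed the
# partition depends on the data values, not the row order. Labels are
# 0-based, matching the raster class encoding.

as_feature_matrix <- function(X) {
  if (is.vector(X) && is.numeric(X)) X <- matrix(X, ncol = 1)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("features must all be finite")
  X
}

# squared distances of every row of X to each center (n x K)
dist2_to_centers <- function(X, centers) {
  K <- nrow(centers)
  d2 <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    diff <- sweep(X, 2L, centers[k, ], `-`)
    d2[, k] <- rowSums(diff * diff)
  }
  d2
}

kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  centers <- matrix(NA_real_, K, ncol(X))
  i <- sample.int(n, 1L)
  centers[1L, ] <- X[i, ]
  if (K > 1L) {
    d2 <- rowSums(sweep(X, 2L, centers[1L, ], `-`)^2)
    for (k in 2L:K) {
      if (all(d2 == 0)) i <- sample.int(n, 1L)
      else i <- sample.int(n, 1L, prob = d2)
      centers[k, ] <- X[i, ]
      d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[k, ], `-`)^2))
    }
  }
  centers
}

#' K-means clustering (Lloyd iterations, k-means++ seeding)
#'
#' Deterministic for a fixed seed, and invariant to observation order:
#' seeding operates on a canonical lexicographic ordering of the rows, so
#' shuffling the input permutes the labels but never changes the partition.
#' Empty clusters are repaired by moving the point farthest from its centroid
#' into the empty cluster.
#'
#' @param X Numeric matrix (rows = observations) or vector (1-D data).
#' @param K Number of clusters, `1 <= K <= nrow(X)`.
#' @param seed Integer seed controlling the probabilistic seeding.
#' @param max_iter Maximum Lloyd iterations (default 300).
#' @param tol Convergence tolerance on centroid movement, in feature units.
#' @return An object of class `cluster_result`: `labels` (0-based integer
#'   vector), `centers` (`K x d`), `sse_per_cluster`, `total_sse`,
#'   `n_iterations`, `sse_history` (SSE after each assignment step),
#'   `repairs` (empty-cluster repairs performed), `flags`.
#' @export
kmeans_fit <- function(X, K, seed = 1L, max_iter = 300L, tol = 1e-6) {
  X <- as_feature_matrix(X)
  n <- nrow(X); K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (n < K) stop(sprintf("need at least K=%d observations, got %d", K, n))

  ord <- do.call(order, c(lapply(seq_len(ncol(X)), function(j) X[, j]),
                          list(method = "radix")))
  Xc <- X[ord, , drop = FALSE]

  centers <- with_seed(seed, kmeanspp_centers(Xc, K))
  labels <- integer(n)
  sse_history <- numeric(0)
  repairs <- 0L
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- dist2_to_centers(Xc, centers)
    labels <- max.col(-d2, ties.method = "first")
    # repair empty clusters with the globally farthest point
    for (k in which(tabulate(labels, K) == 0L)) {
      cur <- d2[cbind(seq_len(n), labels)]
      cur[tabulate(labels, K)[labels] <= 1L] <- -Inf
      far <- which.max(cur)
      labels[far] <- k
      centers[k, ] <- Xc[far, ]
      d2[, k] <- rowSums(sweep(Xc, 2L, centers[k, ], `-`)^2)
      repairs <- repairs + 1L
    }
    sse_history <- c(sse_history,
                     sum(d2[cbind(seq_len(n), labels)]))
    new_centers <- centers
    for (k in seq_len(K))
      new_centers[k, ] <- colMeans(Xc[labels == k, , drop = FALSE])
    movement <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (movement < tol || iter >= max_iter) break
  }
  d2 <- dist2_to_centers(Xc, centers)
  labels <- max.col(-d2, ties.method = "first")
  for (k in which(tabulate(labels, K) == 0L)) {  # guard: keep clusters non-empty
    cur <- d2[cbind(seq_len(n), labels)]
    cur[tabulate(labels, K)[labels] <= 1L] <- -Inf
    far <- which.max(cur)
    labels[far] <- k
    centers[k, ] <- Xc[far, ]
    repairs <- repairs + 1L
  }
  point_sse <- dist2_to_centers(Xc, centers)[cbind(seq_len(n), labels)]
  sse_k <- vapply(seq_len(K), function(k) sum(point_sse[labels == k]), 1)

  labels_orig <- integer(n)
  labels_orig[ord] <- labels - 1L
  structure(list(labels = labels_orig, centers = centers,
                 sse_per_cluster = sse_k, total_sse = sum(sse_k),
                 n_iterations = iter, sse_history = sse_history,
                 repairs = repairs, K = K,
                 flags = character(0)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> K=%d, n=%d, total SSE=%.6g, %d iteration(s)\n",
              x$K, length(x$labels), x$total_sse, x$n_iterations))
  for (k in seq_len(x$K))
    cat(sprintf("  cluster %d: n=%d, centroid=(%s), SSE=%.6g\n", k - 1L,
                sum(x$labels == k - 1L),
                paste(sprintf("%.4g", x$centers[k, ]), collapse = ", "),
                x$sse_per_cluster[k]))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

bisect_seed <- function(seed, split, trial) {
  as.integer((as.numeric(seed) + 7919 * split + 104729 * trial) %% 2147483647)
}

#' Bisecting k-means
#'
#' Divisive clustering: start with all observations in one cluster and
#' repeatedly split the cluster with the highest SSE (ties broken by lowest
#' cluster id) into two with [kmeans_fit()], keeping the best of
#' `n_trial_bisections` restarts by SSE, until `K` clusters exist. Clusters
#' of size 1 cannot be split; if no splittable cluster remains the algorithm
#' stops early with a `"stopped_early"` flag and the achieved K.
#'
#' @inheritParams kmeans_fit
#' @param n_trial_bisections Restarts per bisection (default 5).
#' @return A `cluster_result`; labels `0..K-1` in cluster-creation order.
#' @export
bisecting_kmeans <- function(X, K, seed = 1L, max_iter = 300L, tol = 1e-6,
                             n_trial_bisections = 5L) {
  X <- as_feature_matrix(X)
  n <- nrow(X); K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (n < K) stop(sprintf("need at least K=%d observations, got %d", K, n))

  clusters <- list(seq_len(n))  # row indices per cluster, creation order
  sse_of <- function(idx) {
    Xi <- X[idx, , drop = FALSE]
    ctr <- colMeans(Xi)
    sum(sweep(Xi, 2L, ctr, `-`)^2)
  }
  sses <- sse_of(clusters[[1]])
  sse_history <- sum(sses)  # total SSE at each cluster count 1..K
  flags <- character(0)
  split_no <- 0L

  while (length(clusters) < K) {
    sizes <- lengths(clusters)
    cand <- which(sizes >= 2L)
    if (!length(cand)) {
      flags <- c(flags, "stopped_early")
      warning(sprintf("bisecting k-means stopped at K=%d: no splittable cluster left",
                      length(clusters)))
      break
    }
    target <- cand[which.max(sses[cand])]
    split_no <- split_no + 1L
    idx <- clusters[[target]]
    best <- NULL
    for (trial in seq_len(max(1L, n_trial_bisections))) {
      fit <- kmeans_fit(X[idx, , drop = FALSE], 2L,
                        seed = bisect_seed(seed, split_no, trial),
                        max_iter = max_iter, tol = tol)
      if (is.null(best) || fit$total_sse < best$total_sse) best <- fit
    }
    left <- idx[best$labels == 0L]
    right <- idx[best$labels == 1L]
    clusters[[target]] <- left
    clusters[[length(clusters) + 1L]] <- right
    sses[target] <- sse_of(left)
    sses[length(clusters)] <- sse_of(right)
    sse_history <- c(sse_history, sum(sses))
  }

  Kach <- length(clusters)
  labels <- integer(n)
  for (k in seq_len(Kach)) labels[clusters[[k]]] <- k - 1L
  centers <- do.call(rbind, lapply(clusters, function(idx)
    colMeans(X[idx, , drop = FALSE])))
  structure(list(labels = labels, centers = centers,
                 sse_per_cluster = sses, total_sse = sum(sses),
                 n_iterations = split_no, sse_history = sse_history,
                 repairs = 0L, K = Kach, flags = flags),
            class = "cluster_result")
}
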