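#' Identify the burned cluster of a two-cluster result
#'
#' Difference images are oriented pre-minus-post, so burned pixels show the
#' larger combined index loss: the burned cluster is the one whose centroid
#' has the larger coordinate sum. Ties fall back to the larger first
#' coordinate; an exact tie returns cluster 0 with a warning.
#'
#' @param result A `cluster_result` with `K = 2`.
#' @return Integer cluster id (0 or 1).
#' @export
label_burned_cluster <- function(result) {
  stopifnot(inherits(result, "cluster_result"))
  if (result$K != 2L) stop("expected a two-cluster result")
  s <- rowSums(result$centers)
  if (s[1] != s[2]) return(which.max(s) - 1L)
  if (result$centers[1, 1] != result$centers[2, 1])
    return(which.max(result$centers[, 1]) - 1L)
  warning("cluster centroids coincide; labelling cluster 0 as burned")
  0L
}

# assemble the 2-column feature matrix of valid pixels
burn_features <- function(d1, d2, aoi = NULL) {
  stopifnot(inherits(d1, "difference_image"), inherits(d2, "difference_image"))
  check_same_grid(d1$grid, d2$grid, "difference images")
  valid <- !d1$nodata_mask & !d2$nodata_mask
  if (!is.null(aoi)) {
    stopifnot(is.logical(aoi), all(dim(aoi) == dim(valid)))
    valid <- valid & aoi
  }
  list(valid = valid, X = cbind(d1$values[valid], d2$values[valid]))
}

#' Map the burned area by bisecting k-means
#'
#' Valid (non-nodata, in-AOI) pixels of the two index-difference images form
#' a two-dimensional feature space in which bisecting k-means with `K = 2`
#' separates burned from unburned pixels without any fixed threshold. If the
#' two centroids are closer than `separation_factor` times the pooled
#' within-cluster spread, the split is considered below the noise floor and
#' the result carries a `"low_separation"` flag (an all-constant input gives
#' a no-burn result with the same flag).
#'
#' @param d1,d2 Two [index_difference()] images on one grid (by default the
#'   dNDVI/dYNDVI pair is used upstream).
#' @param aoi Optional logical matrix restricting the analysis.
#' @param seed,max_iter,tol,n_trial_bisections Clustering controls, see
#'   [bisecting_kmeans()].
#' @param separation_factor Noise-floor multiple for the reliability flag
#'   (default 3).
#' @return A list with `mask` (object of class `burn_mask`: `values` logical
#'   matrix with `NA` outside valid pixels, `grid`, `n_burned`, `flags`) and
#'   `clustering` (the `cluster_result`).
#' @export
map_burned_area <- function(d1, d2, aoi = NULL, seed = 1L, max_iter = 300L,
                            tol = 1e-6, n_trial_bisections = 5L,
                            separation_factor = 3) {
  f <- burn_features(d1, d2, aoi)
  n <- nrow(f$X)
  if (n < 2L) stop("fewer than 2 valid pixels; cannot cluster")
  flags <- character(0)

  constant <- all(f$X[, 1] == f$X[1, 1]) && all(f$X[, 2] == f$X[1, 2])
  if (constant) {
    values <- matrix(NA, d1$grid$n_rows, d1$grid$n_cols)
    values[f$valid] <- FALSE
    mask <- structure(list(values = values, grid = d1$grid, n_burned = 0L,
                           flags = c("low_separation", "constant_features")),
                      class = "burn_mask")
    warning("index differences are constant; no burned/unburned structure to separate")
    return(list(mask = mask, clustering = NULL))
  }

  cl <- bisecting_kmeans(f$X, 2L, seed = seed, max_iter = max_iter, tol = tol,
                         n_trial_bisections = n_trial_bisections)
  burned_id <- label_burned_cluster(cl)
  sep <- sqrt(sum((cl$centers[1, ] - cl$centers[2, ])^2))
  noise <- sqrt(cl$total_sse / (n * ncol(f$X)))
  if (sep < separation_factor * noise) {
    flags <- c(flags, "low_separation")
    warning(sprintf(paste0("centroid separation (%.3g) is below %g x the ",
                           "within-cluster spread (%.3g); burned fraction is unreliable"),
                    sep, separation_factor, noise))
  }

  values <- matrix(NA, d1$grid$n_rows, d1$grid$n_cols)
  values[f$valid] <- cl$labels == burned_id
  structure_mask <- structure(list(values = values, grid = d1$grid,
                                   n_burned = sum(cl$labels == burned_id),
                                   flags = flags),
                              class = "burn_mask")
  list(mask = structure_mask, clustering = cl)
}

#' @export
print.burn_mask <- function(x, ...) {
  nvalid <- sum(!is.na(x$values))
  cat(sprintf("<burn_mask> %d / %d valid pixels burned (%.2f%%)\n",
              x$n_burned, nvalid, 100 * x$n_burned / max(1L, nvalid)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Severity class labels
#'
#' The four ordered severity classes, from negligible damage to destroyed.
#' @export
SEVERITY_LABELS <- c("negligible to slight damage", "moderately damaged",
                     "highly damaged", "destroyed")

#' Stratify burned pixels into four severity classes
#'
#' Plain k-means with `K = 4` on the index-difference features of burned
#' pixels only. Clusters are ordered by ascending centroid coordinate sum and
#' mapped to severity classes 0 (negligible-to-slight) through 3 (destroyed):
#' the larger the combined index loss, the higher the severity.
#'
#' @param d1,d2 The difference images used for the burn mask.
#' @param mask A `burn_mask` from [map_burned_area()].
#' @param seed,max_iter,tol Clustering controls.
#' @return A list with `severity` (object of class `severity_map`: `values`
#'   integer matrix with classes 0-3 on burned pixels and `NA` elsewhere,
#'   `grid`, `class_counts`, `labels`, `flags`) and `clustering`. If fewer
#'   than 4 burned pixels exist, severity is skipped (`NULL`) with a warning.
#' @export
map_severity <- function(d1, d2, mask, seed = 1L, max_iter = 300L,
                         tol = 1e-6) {
  stopifnot(inherits(mask, "burn_mask"))
  check_same_grid(d1$grid, mask$grid, "difference image and burn mask")
  burned <- !is.na(mask$values) & mask$values
  if (sum(burned) < 4L) {
    warning("fewer than 4 burned pixels; severity mapping skipped")
    return(list(severity = NULL, clustering = NULL))
  }
  X <- cbind(d1$values[burned], d2$values[burned])
  flags <- character(0)
  n_distinct <- nrow(unique(X))
  cl <- kmeans_fit(X, 4L, seed = seed, max_iter = max_iter, tol = tol)
  if (cl$repairs > 0L || n_distinct < 4L) flags <- c(flags, "degenerate")

  ord <- order(rowSums(cl$centers), cl$centers[, 1])
  class_of_cluster <- integer(4L)
  class_of_cluster[ord] <- 0:3
  classes <- class_of_cluster[cl$labels + 1L]

  values <- matrix(NA_integer_, d1$grid$n_rows, d1$grid$n_cols)
  values[burned] <- classes
  counts <- tabulate(classes + 1L, 4L)
  sev <- structure(list(values = values, grid = d1$grid,
                        class_counts = counts, labels = SEVERITY_LABELS,
                        flags = flags),
                   class = "severity_map")
  list(severity = sev, clustering = cl)
}

#' @export
print.severity_map <- function(x, ...) {
  cat("<severity_map> class pixel counts:\n")
  for (k in 1:4)
    cat(sprintf("  %d %-28s %d\n", k - 1L, x$labels[k], x$class_counts[k]))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
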