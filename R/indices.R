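# Vegetation index registry. Each entry: the semantic bands required and the
# per-pixel formula. All inputs are surface reflectance; outputs are
# dimensionless index values. Zero denominators yield nodata (explicit over
# clamped). MSR is implemented in the linear form (NIR/RED - 1)/(NIR/RED + 1),
# which is algebraically NDVI; the square-root variant found elsewhere in the
# literature is deliberately not provided (single behaviour, see vignette).
INDEX_REGISTRY <- list(
  EVI = list(bands = c("NIR", "RED", "BLUE"),
             fn = function(b, p) {
               den <- b$NIR + 6 * b$RED - 7.5 * b$BLUE + 1
               2.5 * (b$NIR - b$RED) / den
             }),
  GEMI = list(bands = c("NIR", "RED"),
              fn = function(b, p) {
                n <- (2 * (b$NIR^2 - b$RED^2) + 1.5 * b$NIR + 0.5 * b$RED) /
                  (b$NIR + b$RED + 0.5)
                n * (1 - 0.25 * n) - (b$RED - 0.125) / (1 - b$RED)
              }),
  GNDVI1 = list(bands = c("NIR", "GREEN_I"),
                fn = function(b, p) (b$NIR - b$GREEN_I) / (b$NIR + b$GREEN_I)),
  GNDVI2 = list(bands = c("NIR", "GREEN"),
                fn = function(b, p) (b$NIR - b$GREEN) / (b$NIR + b$GREEN)),
  MSR = list(bands = c("NIR", "RED"),
             fn = function(b, p) {
               rdvi <- b$NIR / b$RED
               (rdvi - 1) / (rdvi + 1)
             }),
  NDVI = list(bands = c("NIR", "RED"),
              fn = function(b, p) (b$NIR - b$RED) / (b$NIR + b$RED)),
  SR = list(bands = c("NIR", "RED"), fn = function(b, p) b$NIR / b$RED),
  SAVI = list(bands = c("NIR", "RED"),
              fn = function(b, p) 1.5 * (b$NIR - b$RED) / (b$NIR + b$RED + 0.5)),
  WDRVI = list(bands = c("NIR", "RED"),
               fn = function(b, p) (p$wdrvi_a * b$NIR - b$RED) /
                 (p$wdrvi_a * b$NIR + b$RED)),
  YNDVI = list(bands = c("NIR", "YELLOW"),
               fn = function(b, p) (b$NIR - b$YELLOW) / (b$NIR + b$YELLOW))
)

#' Names of the supported vegetation indices
#'
#' The nine indices of the screening stage; the green normalized difference
#' index appears twice because the sensor has two green bands (`GNDVI1` uses
#' GREEN_I, 513-549 nm; `GNDVI2` uses GREEN, 547-583 nm).
#'
#' @return Character vector.
#' @export
index_names <- function() names(INDEX_REGISTRY)

#' Compute a vegetation index on a scene
#'
#' Evaluates one of the supported index formulas per pixel. Pixels where the
#' formula's denominator is zero (or the input is nodata) are flagged nodata.
#'
#' @param x A [scene()].
#' @param index_name One of [index_names()].
#' @param wdrvi_a Weighting coefficient `a` of WDRVI, in `[0.1, 0.2]`.
#' @return An object of class `index_image`: list with `values` (numeric
#'   matrix), `index_name`, `nodata_mask`, `grid`.
#' @export
compute_index <- function(x, index_name, wdrvi_a = 0.1) {
  stopifnot(inherits(x, "fire_scene"))
  if (!index_name %in% names(INDEX_REGISTRY))
    stop("unknown index: ", index_name)
  if (index_name == "WDRVI" && (wdrvi_a < 0.1 || wdrvi_a > 0.2))
    stop("wdrvi_a must lie in [0.1, 0.2]")
  reg <- INDEX_REGISTRY[[index_name]]
  missing <- setdiff(reg$bands, names(x$band_map))
  if (length(missing))
    stop(sprintf("index %s needs band(s) %s not present in the scene's band map",
                 index_name, paste(missing, collapse = ", ")))
  b <- stats::setNames(lapply(reg$bands, scene_band, x = x), reg$bands)
  vals <- reg$fn(b, list(wdrvi_a = wdrvi_a))
  nodata <- x$nodata_mask | !is.finite(vals)
  vals[nodata] <- NA_real_
  structure(list(values = vals, index_name = index_name,
                 nodata_mask = nodata, grid = x$grid),
            class = "index_image")
}

#' Pre-minus-post index difference
#'
#' Difference images are oriented so that vegetation loss is positive:
#' `values = pre - post`. Nodata is the union of both inputs' nodata.
#'
#' @param pre,post Two `index_image`s of the same index on the same grid.
#' @return An object of class `difference_image` (same fields as
#'   `index_image`).
#' @export
index_difference <- function(pre, post) {
  stopifnot(inherits(pre, "index_image"), inherits(post, "index_image"))
  if (!identical(pre$index_name, post$index_name))
    stop("cannot difference distinct indices: ", pre$index_name, " vs ",
         post$index_name)
  check_same_grid(pre$grid, post$grid, "pre/post index images")
  nodata <- pre$nodata_mask | post$nodata_mask
  vals <- pre$values - post$values
  vals[nodata] <- NA_real_
  structure(list(values = vals, index_name = pre$index_name,
                 nodata_mask = nodata, grid = pre$grid),
            class = "difference_image")
}

#' Mean index difference within a mask
#'
#' Arithmetic mean of the difference image over pixels where `mask` is `TRUE`
#' and the difference is valid; the screening statistic behind index
#' selection.
#'
#' @param diff A [index_difference()] result.
#' @param mask Logical matrix of the grid shape.
#' @return A single number.
#' @export
masked_mean_difference <- function(diff, mask) {
  stopifnot(inherits(diff, "difference_image"), is.logical(mask))
  if (!all(dim(mask) == dim(diff$values)))
    stop("mask shape does not match the difference image")
  sel <- mask & !diff$nodata_mask
  if (!any(sel)) stop("mask selects no valid pixels")
  mean(diff$values[sel])
}

#' Screen vegetation indices by masked mean difference
#'
#' Computes every supported index on both scenes, differences them
#' (pre minus post), and averages each difference over the mask. Indices
#' whose bands are missing from the band map are omitted with a warning.
#' Rows are sorted by descending mean difference (ties by name).
#'
#' @param pre,post Pre- and post-fire [scene()]s on one grid.
#' @param mask Logical matrix (e.g. a rasterized reference delimitation);
#'   `NULL` averages over all valid pixels.
#' @param wdrvi_a Passed to [compute_index()].
#' @return A `data.frame` with columns `index_name`, `mean_difference`,
#'   `n_pixels`.
#' @export
screen_indices <- function(pre, post, mask = NULL, wdrvi_a = 0.1) {
  stopifnot(inherits(pre, "fire_scene"), inherits(post, "fire_scene"))
  check_same_grid(pre$grid, post$grid, "pre/post scenes")
  if (is.null(mask)) mask <- matrix(TRUE, pre$grid$n_rows, pre$grid$n_cols)
  rows <- list()
  for (nm in index_names()) {
    reg <- INDEX_REGISTRY[[nm]]
    if (!all(reg$bands %in% names(pre$band_map)) ||
        !all(reg$bands %in% names(post$band_map))) {
      warning("skipping ", nm, ": required band(s) missing from the band map")
      next
    }
    d <- index_difference(compute_index(pre, nm, wdrvi_a),
                          compute_index(post, nm, wdrvi_a))
    sel <- mask & !d$nodata_mask
    rows[[nm]] <- data.frame(index_name = nm,
                             mean_difference = mean(d$values[sel]),
                             n_pixels = sum(sel))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(-out$mean_difference, out$index_name), , drop = FALSE]
}
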