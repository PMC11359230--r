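#' Slope from a DEM (Horn's method)
#'
#' Eight-neighbour finite differences with the 3x3 Horn kernel; slope is
#' `atan(|grad z|)` in degrees. Border pixels use edge replication. The DEM
#' grid must have metric pixel sizes (reproject geographic DEMs upstream);
#' non-finite elevations propagate as `NA` slope over their 3x3 window.
#'
#' @param dem Numeric matrix of elevations in metres.
#' @param grid A [grid_geometry()] for the DEM with pixel sizes in metres.
#' @return Numeric matrix of slope angles in degrees, `[0, 90)`.
#' @export
compute_slope <- function(dem, grid) {
  stopifnot(is.matrix(dem), inherits(grid, "grid_geometry"))
  if (nrow(dem) != grid$n_rows || ncol(dem) != grid$n_cols)
    stop("DEM shape does not match its grid geometry")
  nr <- nrow(dem); nc <- ncol(dem)
  if (nr < 3L || nc < 3L) stop("DEM must be at least 3 x 3 pixels")

  # edge-replicated padding
  z <- rbind(dem[1, , drop = FALSE], dem, dem[nr, , drop = FALSE])
  z <- cbind(z[, 1, drop = FALSE], z, z[, nc, drop = FALSE])
  sh <- function(dr, dc) z[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]

  gx <- ((sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
           (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))) / (8 * grid$pixel_size_x)
  gy <- ((sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
           (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))) / (8 * grid$pixel_size_y)
  slope <- atan(sqrt(gx * gx + gy * gy)) * 180 / pi
  slope[!is.finite(slope)] <- NA_real_
  slope[!is.finite(dem)] <- NA_real_
  slope
}

#' Resample a slope plane onto the scene grid
#'
#' Bilinear interpolation at scene pixel centres (cell-centre registration on
#' both grids); exact for linear slope fields. Scene pixels outside the DEM's
#' interpolable extent get slope 0 and the result carries a
#' `partial_coverage` attribute.
#'
#' @param slope Slope matrix on the DEM grid (degrees).
#' @param dem_grid DEM [grid_geometry()].
#' @param target Scene [grid_geometry()] (same CRS as the DEM).
#' @return Slope matrix on the target grid, with attribute
#'   `partial_coverage` (`TRUE`/`FALSE`).
#' @export
resample_slope <- function(slope, dem_grid, target) {
  stopifnot(is.matrix(slope), inherits(dem_grid, "grid_geometry"),
            inherits(target, "grid_geometry"))
  if (nzchar(dem_grid$crs) && nzchar(target$crs) &&
      !identical(toupper(dem_grid$crs), toupper(target$crs)))
    stop("DEM and scene CRS differ; reproject the DEM first")
  ctr <- pixel_centers(target)
  # fractional DEM pixel indices (1-based, cell centres) of scene centres
  fc <- (ctr$x - dem_grid$origin_x) / dem_grid$pixel_size_x + 0.5
  fr <- (dem_grid$origin_y - ctr$y) / dem_grid$pixel_size_y + 0.5

  nr <- nrow(slope); nc <- ncol(slope)
  inside_r <- fr >= 1 & fr <= nr
  inside_c <- fc >= 1 & fc <= nc
  if (!any(inside_r) || !any(inside_c))
    stop("DEM does not overlap the target grid")

  r0 <- pmin(pmax(floor(fr), 1L), nr - 1L)
  c0 <- pmin(pmax(floor(fc), 1L), nc - 1L)
  wr <- pmin(pmax(fr - r0, 0), 1)
  wc <- pmin(pmax(fc - c0, 0), 1)

  R0 <- matrix(r0, target$n_rows, target$n_cols)
  C0 <- matrix(c0, target$n_rows, target$n_cols, byrow = TRUE)
  WR <- matrix(wr, target$n_rows, target$n_cols)
  WC <- matrix(wc, target$n_rows, target$n_cols, byrow = TRUE)
  at <- function(dr, dc) slope[cbind(c(R0) + dr, c(C0) + dc)]
  # lerp form: exact (to the ulp) for constant fields
  top <- at(0L, 0L) + c(WC) * (at(0L, 1L) - at(0L, 0L))
  bot <- at(1L, 0L) + c(WC) * (at(1L, 1L) - at(1L, 0L))
  out <- matrix(top + c(WR) * (bot - top), target$n_rows, target$n_cols)

  covered <- outer(inside_r, inside_c, `&`)
  partial <- !all(covered)
  out[!covered] <- 0
  attr(out, "partial_coverage") <- partial
  out
}

#' Per-pixel slope weights for surface-area correction
#'
#' The true ground surface of a pixel exceeds its planimetric footprint by
#' the factor `1 / cos(slope)`; weights are therefore `>= 1`, with 1 on flat
#' terrain. `NA` slopes fall back to weight 1.
#'
#' @param slope Slope matrix in degrees on the scene grid, or `NULL` for flat
#'   (planimetric) weighting.
#' @param grid Scene [grid_geometry()].
#' @return An object of class `slope_weights`: `slope`, `weight`, `grid`,
#'   `flags`.
#' @export
slope_weights <- function(slope, grid) {
  stopifnot(inherits(grid, "grid_geometry"))
  flags <- character(0)
  if (is.null(slope)) {
    slope <- matrix(0, grid$n_rows, grid$n_cols)
    flags <- "no_dem"
  }
  stopifnot(is.matrix(slope), nrow(slope) == grid$n_rows,
            ncol(slope) == grid$n_cols)
  if (any(is.finite(slope) & (slope < 0 | slope >= 90)))
    stop("slope angles must lie in [0, 90) degrees")
  if (isTRUE(attr(slope, "partial_coverage")))
    flags <- c(flags, "partial_dem_coverage")
  w <- 1 / cos(slope * pi / 180)
  w[!is.finite(w)] <- 1
  structure(list(slope = slope, weight = w, grid = grid, flags = flags),
            class = "slope_weights")
}

#' Slope-weighted surface area of a mask, in hectares
#'
#' `area = sum over TRUE pixels of pixel_size_x * pixel_size_y * weight /
#' 10000`. With `weights = NULL` every weight is 1 (planimetric area).
#'
#' @param mask A `burn_mask` or a logical matrix.
#' @param weights A [slope_weights()] on the same grid, or `NULL`.
#' @param grid Required when `mask` is a plain matrix.
#' @return Area in hectares.
#' @export
weighted_area <- function(mask, weights = NULL, grid = NULL) {
  if (inherits(mask, "burn_mask")) {
    grid <- mask$grid
    mask <- !is.na(mask$values) & mask$values
  }
  stopifnot(is.logical(mask), inherits(grid, "grid_geometry"),
            nrow(mask) == grid$n_rows, ncol(mask) == grid$n_cols)
  mask[is.na(mask)] <- FALSE
  px_area <- grid$pixel_size_x * grid$pixel_size_y
  if (is.null(weights)) return(sum(mask) * px_area / 1e4)
  stopifnot(inherits(weights, "slope_weights"))
  check_same_grid(grid, weights$grid, "mask and slope weights")
  sum(weights$weight[mask]) * px_area / 1e4
}
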