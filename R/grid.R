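#' Grid geometry of a georeferenced raster
#'
#' Describes the common pixel grid all rasters in a run share: shape, pixel
#' size in map units (metres for projected CRSs), the map coordinate of the
#' upper-left corner of the upper-left pixel, and a CRS identifier.
#'
#' Conventions: pixel `(1,1)` is the upper-left pixel; rows increase
#' southward; the map coordinate associated with a pixel is its centre.
#'
#' @param n_rows,n_cols Raster shape, both `>= 1`.
#' @param pixel_size_x,pixel_size_y Pixel size in map units, strictly positive.
#' @param origin_x,origin_y Map coordinates of the upper-left corner of the
#'   upper-left pixel (not its centre).
#' @param crs Coordinate reference system identifier, e.g. `"EPSG:32634"`.
#' @return An object of class `grid_geometry`.
#' @export
grid_geometry <- function(n_rows, n_cols, pixel_size_x, pixel_size_y,
                          origin_x = 0, origin_y = n_rows * pixel_size_y,
                          crs = "") {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L)
    stop("grid must have at least one row and one column")
  if (!is.finite(pixel_size_x) || !is.finite(pixel_size_y) ||
      pixel_size_x <= 0 || pixel_size_y <= 0)
    stop("pixel sizes must be strictly positive")
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 pixel_size_x = as.numeric(pixel_size_x),
                 pixel_size_y = as.numeric(pixel_size_y),
                 origin_x = as.numeric(origin_x),
                 origin_y = as.numeric(origin_y),
                 crs = as.character(crs)),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry> %d x %d pixels, %g x %g map units/pixel\n",
              x$n_rows, x$n_cols, x$pixel_size_x, x$pixel_size_y))
  cat(sprintf("  origin (UL corner): (%.6g, %.6g)  crs: %s\n",
              x$origin_x, x$origin_y,
              if (nzchar(x$crs)) x$crs else "<unset>"))
  invisible(x)
}

#' Map coordinates of pixel centres
#'
#' @param grid A [grid_geometry()].
#' @return A list with numeric vectors `x` (length `n_cols`, west to east) and
#'   `y` (length `n_rows`, north to south).
#' @export
pixel_centers <- function(grid) {
  stopifnot(inherits(grid, "grid_geometry"))
  list(x = grid$origin_x + (seq_len(grid$n_cols) - 0.5) * grid$pixel_size_x,
       y = grid$origin_y - (seq_len(grid$n_rows) - 0.5) * grid$pixel_size_y)
}

#' Test two grids for equality within a fractional-pixel tolerance
#'
#' Pre- and post-fire scenes must already be co-registered on one grid; the
#' package verifies this and aborts rather than resampling imagery silently.
#'
#' @param a,b Two [grid_geometry()] objects.
#' @param tol Tolerance, as a fraction of a pixel (default `1e-6`).
#' @return `TRUE` or `FALSE`.
#' @export
grids_equal <- function(a, b, tol = 1e-6) {
  stopifnot(inherits(a, "grid_geometry"), inherits(b, "grid_geometry"))
  if (a$n_rows != b$n_rows || a$n_cols != b$n_cols) return(FALSE)
  px <- max(a$pixel_size_x, b$pixel_size_x)
  py <- max(a$pixel_size_y, b$pixel_size_y)
  abs(a$pixel_size_x - b$pixel_size_x) <= tol * px &&
    abs(a$pixel_size_y - b$pixel_size_y) <= tol * py &&
    abs(a$origin_x - b$origin_x) <= tol * px &&
    abs(a$origin_y - b$origin_y) <= tol * py
}

check_same_grid <- function(a, b, what = "rasters") {
  if (!grids_equal(a, b))
    stop(sprintf("%s are not on the same grid (shape, pixel size and origin must agree within 1e-6 of a pixel)", what))
  invisible(TRUE)
}

# Run expr with a private, restored RNG state seeded by `seed`.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  expr
}
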