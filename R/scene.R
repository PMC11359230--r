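#' Semantic band names of a SuperDove-class sensor
#'
#' The eight-band surface-reflectance layout: coastal blue, blue, green I,
#' green, yellow, red, red edge and near infrared. A [scene()] may carry any
#' subset, declared through its band map.
#'
#' @export
SUPERDOVE_BANDS <- c("COASTAL_BLUE", "BLUE", "GREEN_I", "GREEN",
                     "YELLOW", "RED", "RED_EDGE", "NIR")

#' Default SuperDove band map
#'
#' Maps the semantic names in [SUPERDOVE_BANDS] to band positions 1..8, the
#' standard layout of the 8-band surface-reflectance product.
#'
#' @return Named integer vector.
#' @export
superdove_band_map <- function() {
  stats::setNames(seq_along(SUPERDOVE_BANDS), SUPERDOVE_BANDS)
}

#' Construct a multispectral scene
#'
#' A scene is a georeferenced stack of reflectance planes plus a band map
#' resolving semantic band names to plane positions and a shared nodata mask.
#' Reflectance is unitless surface reflectance, nominally in `[0, 1]`.
#'
#' @param bands List of numeric matrices, one per band, sharing one shape.
#' @param grid A [grid_geometry()] matching the planes.
#' @param band_map Named integer vector, e.g. `c(NIR = 8, RED = 6)`; every
#'   name must resolve to exactly one existing band.
#' @param nodata_mask Logical matrix, `TRUE` where pixels are invalid;
#'   defaults to all valid.
#' @return An object of class `fire_scene`.
#' @export
scene <- function(bands, grid, band_map, nodata_mask = NULL) {
  if (is.matrix(bands)) bands <- list(bands)
  stopifnot(inherits(grid, "grid_geometry"), length(bands) >= 1)
  if (!all(vapply(bands, is.matrix, TRUE)))
    stop("bands must be a list of matrices")
  nr <- grid$n_rows; nc <- grid$n_cols
  if (!all(vapply(bands, function(b) nrow(b) == nr && ncol(b) == nc, TRUE)))
    stop("all band planes must share the grid shape")
  if (is.null(names(band_map)) || anyDuplicated(names(band_map)))
    stop("band_map must have unique semantic names")
  band_map <- stats::setNames(as.integer(band_map), names(band_map))
  if (any(band_map < 1L | band_map > length(bands)))
    stop("band_map refers to band positions that do not exist")
  unknown <- setdiff(names(band_map), SUPERDOVE_BANDS)
  if (length(unknown))
    stop("unknown semantic band name(s): ", paste(unknown, collapse = ", "))
  if (is.null(nodata_mask)) nodata_mask <- matrix(FALSE, nr, nc)
  stopifnot(is.logical(nodata_mask), nrow(nodata_mask) == nr,
            ncol(nodata_mask) == nc)
  nodata_mask[is.na(nodata_mask)] <- TRUE
  for (b in bands) {
    bad <- !is.finite(b) & !nodata_mask
    if (any(bad))
      stop("non-finite reflectance outside the nodata mask; flag those pixels as nodata")
  }
  structure(list(bands = bands, grid = grid, band_map = band_map,
                 nodata_mask = nodata_mask),
            class = "fire_scene")
}

#' @export
print.fire_scene <- function(x, ...) {
  cat(sprintf("<fire_scene> %d band(s) on a %d x %d grid (%g x %g map units/pixel)\n",
              length(x$bands), x$grid$n_rows, x$grid$n_cols,
              x$grid$pixel_size_x, x$grid$pixel_size_y))
  cat("  bands:", paste(sprintf("%s=%d", names(x$band_map), x$band_map),
                        collapse = ", "), "\n")
  cat(sprintf("  nodata pixels: %d / %d\n", sum(x$nodata_mask),
              length(x$nodata_mask)))
  invisible(x)
}

#' Extract a semantic band plane from a scene
#'
#' @param x A [scene()].
#' @param name A semantic band name, e.g. `"NIR"`.
#' @return Numeric matrix of reflectance.
#' @export
scene_band <- function(x, name) {
  stopifnot(inherits(x, "fire_scene"))
  if (!name %in% names(x$band_map))
    stop("band ", name, " is not declared in this scene's band map")
  x$bands[[x$band_map[[name]]]]
}

#' Read a multispectral scene from a GeoTIFF
#'
#' Stored digital numbers are converted to surface reflectance by
#' `reflectance = stored * scale_factor`. The default factor `1e-4` matches
#' integer-scaled surface-reflectance products; pass `1` for rasters already
#' stored as reflectance.
#'
#' @param path GeoTIFF path.
#' @param band_map Named integer vector mapping semantic band names to band
#'   positions in the file (default: the 8-band SuperDove layout).
#' @param scale_factor Positive multiplicative factor applied to stored values.
#' @return A [scene()].
#' @export
read_scene <- function(path, band_map = superdove_band_map(),
                       scale_factor = 1e-4) {
  if (!is.numeric(scale_factor) || scale_factor <= 0)
    stop("scale_factor must be > 0")
  r <- read_geotiff(path)
  if (any(band_map > length(r$planes)))
    stop(sprintf("band_map asks for band %d but %s has only %d band(s)",
                 max(band_map), path, length(r$planes)))
  nodata <- Reduce(`|`, lapply(r$planes, function(p) {
    m <- !is.finite(p)
    if (is.finite(r$nodata)) m | (p == r$nodata) else m
  }))
  planes <- lapply(r$planes, function(p) {
    p <- p * scale_factor
    p[nodata] <- NA_real_
    p
  })
  scene(planes, r$grid, band_map, nodata_mask = nodata)
}

#' Write raster planes to GeoTIFF
#'
#' Continuous planes are stored as 32-bit floats with NaN nodata; logical and
#' categorical planes as unsigned 8-bit integers with nodata code 255.
#'
#' @param x A matrix (one band) or list of matrices; logical matrices are
#'   encoded `{0,1}`, `NA` as 255.
#' @param path Output path.
#' @param grid A [grid_geometry()].
#' @param type Storage type; `NULL` picks `"UInt8"` for logical/categorical
#'   input and `"Float32"` otherwise.
#' @return `path`, invisibly.
#' @export
write_raster <- function(x, path, grid, type = NULL) {
  if (is.matrix(x)) x <- list(x)
  categorical <- all(vapply(x, function(p)
    is.logical(p) || (is.numeric(p) && all(p[is.finite(p)] == round(p[is.finite(p)])) &&
                        all(p[is.finite(p)] >= 0 & p[is.finite(p)] <= 254)), TRUE))
  if (is.null(type)) type <- if (categorical) "UInt8" else "Float32"
  x <- lapply(x, function(p) { storage.mode(p) <- "double"; p })
  nodata <- if (type %in% c("Float32", "Float64")) NULL else 255
  write_geotiff(x, path, grid, type = type, nodata = nodata)
}
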