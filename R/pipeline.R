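#' Map burned area and fire severity from a pre/post scene pair
#'
#' The package's main entry point. Runs the full methodology on two
#' co-registered scenes: computes the selected vegetation-index pair on both
#' scenes, forms pre-minus-post differences, separates burned from unburned
#' pixels with bisecting k-means (`K = 2`) in the two-dimensional
#' index-difference space, stratifies burned pixels into four ordered
#' severity classes with k-means (`K = 4`), derives per-pixel
#' `1/cos(slope)` surface weights from an optional DEM, and reports
#' slope-corrected burned hectares, severity shares, and (when a reference
#' delimitation is given) the area discrepancy.
#'
#' @param pre,post Pre- and post-fire [scene()]s on one grid.
#' @param dem Optional DEM: a list with `dem` (elevation matrix, metres) and
#'   `grid` (its [grid_geometry()]), e.g. from [simulate_dem()] or
#'   [read_geotiff()].
#' @param aoi Optional area of interest: a [vector_mask()] or a logical
#'   matrix on the scene grid.
#' @param reference Optional reference delimitation: a [vector_mask()] or a
#'   number (hectares).
#' @param index_pair Two index names from [index_names()] (default
#'   `c("NDVI", "YNDVI")`, the pair selected by screening).
#' @param wdrvi_a WDRVI coefficient, see [compute_index()].
#' @param seed,max_iter,tol,n_trial_bisections Clustering controls.
#' @return An object of class `fire_map`: list with `mask` (`burn_mask`),
#'   `severity` (`severity_map` or `NULL`), `weights` ([slope_weights()]),
#'   `report` ([area_report()]), `differences` (the two difference images),
#'   `clustering` (burn and severity `cluster_result`s), `call`.
#' @examples
#' sim <- simulate_fire_scene(n_rows = 60, n_cols = 60, seed = 7)
#' fm <- fire_map(sim$pre, sim$post, seed = 7)
#' print(fm)
#' @export
fire_map <- function(pre, post, dem = NULL, aoi = NULL, reference = NULL,
                     index_pair = c("NDVI", "YNDVI"), wdrvi_a = 0.1,
                     seed = 1L, max_iter = 300L, tol = 1e-6,
                     n_trial_bisections = 5L) {
  stopifnot(inherits(pre, "fire_scene"), inherits(post, "fire_scene"))
  check_same_grid(pre$grid, post$grid, "pre/post scenes")
  index_pair <- as.character(index_pair)
  if (length(index_pair) != 2L || index_pair[1] == index_pair[2])
    stop("index_pair must name two distinct indices")
  grid <- pre$grid

  aoi_plane <- NULL
  if (!is.null(aoi)) {
    aoi_plane <- if (inherits(aoi, "vector_mask")) rasterize_mask(aoi, grid)
                 else aoi
    stopifnot(is.logical(aoi_plane))
  }

  d <- lapply(index_pair, function(nm)
    index_difference(compute_index(pre, nm, wdrvi_a),
                     compute_index(post, nm, wdrvi_a)))

  burn <- map_burned_area(d[[1]], d[[2]], aoi = aoi_plane, seed = seed,
                          max_iter = max_iter, tol = tol,
                          n_trial_bisections = n_trial_bisections)
  flags <- burn$mask$flags

  sev <- list(severity = NULL, clustering = NULL)
  if (burn$mask$n_burned >= 4L) {
    sev <- map_severity(d[[1]], d[[2]], burn$mask, seed = seed,
                        max_iter = max_iter, tol = tol)
    if (!is.null(sev$severity)) flags <- union(flags, sev$severity$flags)
  } else if (burn$mask$n_burned > 0L) {
    flags <- union(flags, "severity_skipped")
  }

  if (!is.null(dem)) {
    slope_dem <- compute_slope(dem$dem, dem$grid)
    slope_scene <- resample_slope(slope_dem, dem$grid, grid)
    w <- slope_weights(slope_scene, grid)
  } else {
    w <- slope_weights(NULL, grid)
  }
  flags <- union(flags, w$flags)

  est_ha <- weighted_area(burn$mask, weights = w)
  ref_ha <- NULL
  if (!is.null(reference)) {
    ref_ha <- if (inherits(reference, "vector_mask"))
      reference_area_from_mask(reference, grid, weights = w)
    else as.numeric(reference)
  }
  sev_pct <- if (!is.null(sev$severity))
    severity_percentages(sev$severity, weights = w) else NULL

  diagnostics <- list(
    index_pair = index_pair, seed = seed,
    burn_clustering = cluster_diag(burn$clustering),
    severity_clustering = cluster_diag(sev$clustering))
  report <- area_report(est_ha, reference_ha = ref_ha,
                        severity_pct = sev_pct, flags = flags,
                        diagnostics = diagnostics)
  structure(list(mask = burn$mask, severity = sev$severity, weights = w,
                 report = report, differences = d,
                 clustering = list(burn = burn$clustering,
                                   severity = sev$clustering),
                 grid = grid, call = match.call()),
            class = "fire_map")
}

cluster_diag <- function(cl) {
  if (is.null(cl)) return(NULL)
  list(K = cl$K, centroids = unname(apply(cl$centers, 1, as.numeric,
                                          simplify = FALSE)),
       sse_per_cluster = cl$sse_per_cluster, total_sse = cl$total_sse,
       n_iterations = cl$n_iterations, flags = cl$flags)
}

#' @export
print.fire_map <- function(x, ...) {
  cat("Burned-area / fire-severity map\n")
  nvalid <- sum(!is.na(x$mask$values))
  cat(sprintf("  grid: %d x %d pixels at %g x %g m\n", x$grid$n_rows,
              x$grid$n_cols, x$grid$pixel_size_x, x$grid$pixel_size_y))
  cat(sprintf("  burned: %d / %d valid pixels (%.2f%%)\n", x$mask$n_burned,
              nvalid, 100 * x$mask$n_burned / max(1L, nvalid)))
  cat(sprintf("  estimated burned surface: %.2f ha%s\n",
              x$report$estimated_burned_ha,
              if ("no_dem" %in% x$report$flags) " (planimetric, no DEM)" else
                " (slope-corrected)"))
  invisible(x)
}

#' @export
summary.fire_map <- function(object, ...) {
  print(object)
  print(object$report)
  if (!is.null(object$clustering$burn)) {
    cat("Burned/unburned clustering:\n")
    print(object$clustering$burn)
  }
  invisible(object)
}

#' Plot a fire map
#'
#' Two panels: the burned-area mask and, when available, the severity map
#' coloured from light yellow (negligible) to dark red (destroyed).
#'
#' @param x A `fire_map`.
#' @param ... Ignored.
#' @export
plot.fire_map <- function(x, ...) {
  flip <- function(m) t(m[nrow(m):1, , drop = FALSE])
  old <- graphics::par(mfrow = c(1, if (is.null(x$severity)) 1 else 2),
                       mar = c(1, 1, 2, 1))
  on.exit(graphics::par(old))
  m <- x$mask$values; m[is.na(m)] <- FALSE
  graphics::image(flip(m), col = c("grey90", "black"), axes = FALSE,
                  main = "burned area", useRaster = TRUE)
  if (!is.null(x$severity)) {
    graphics::image(flip(x$severity$values),
                    col = c("#ffffb2", "#fd8d3c", "#e31a1c", "#67000d"),
                    zlim = c(0, 3), axes = FALSE, main = "severity",
                    useRaster = TRUE)
  }
  invisible(x)
}

#' Run the end-to-end pipeline on files and write all artifacts
#'
#' File-level orchestration of [fire_map()]: reads the scenes (and optional
#' DEM / AOI / reference delimitation), runs the method, and writes
#' `burn_mask.tif`, `severity.tif`, `slope.tif` + `weight.tif` (if a DEM was
#' given), `screening.csv` and `report.json` into `out_dir`. On any stage
#' error, partial outputs are removed.
#'
#' @param cfg A named list (or path to a `key = value` text file) with
#'   entries: `pre`, `post` (GeoTIFF paths, required), `dem`, `aoi`,
#'   `reference` (optional paths; `reference` may also be a number in
#'   hectares), `out_dir` (required), `band_map` (defaults to the 8-band
#'   layout), `scale_factor` (default 1e-4), `index_pair` (default
#'   `NDVI,YNDVI`), `wdrvi_a`, `seed`, `tol`, `max_iter`,
#'   `n_trial_bisections`, `crs` (CRS assumed for GeoJSON inputs).
#' @return The `fire_map` object, invisibly.
#' @export
run_pipeline <- function(cfg) {
  cfg <- load_run_config(cfg)
  for (key in c("pre", "post", "out_dir"))
    if (is.null(cfg[[key]])) stop("run config lacks required entry: ", key)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  on_error <- function(e) {
    unlink(written)
    stop(e)
  }
  tryCatch({
    pre <- read_scene(cfg$pre, band_map = cfg$band_map,
                      scale_factor = cfg$scale_factor)
    post <- read_scene(cfg$post, band_map = cfg$band_map,
                       scale_factor = cfg$scale_factor)
    dem <- if (!is.null(cfg$dem)) {
      r <- read_geotiff(cfg$dem)
      list(dem = r$planes[[1]], grid = r$grid)
    }
    aoi <- if (!is.null(cfg$aoi))
      read_vector_mask(cfg$aoi, role = "aoi", crs = pre$grid$crs)
    reference <- if (!is.null(cfg$reference)) {
      if (is.character(cfg$reference) && file.exists(cfg$reference))
        read_vector_mask(cfg$reference, role = "reference_delimitation",
                         crs = pre$grid$crs)
      else as.numeric(cfg$reference)
    }

    fm <- fire_map(pre, post, dem = dem, aoi = aoi, reference = reference,
                   index_pair = cfg$index_pair, wdrvi_a = cfg$wdrvi_a,
                   seed = cfg$seed, max_iter = cfg$max_iter, tol = cfg$tol,
                   n_trial_bisections = cfg$n_trial_bisections)

    p <- function(name) file.path(cfg$out_dir, name)
    mask_vals <- fm$mask$values * 1
    write_raster(mask_vals, p("burn_mask.tif"), fm$grid)
    written <- c(written, p("burn_mask.tif"))
    if (!is.null(fm$severity)) {
      write_raster(fm$severity$values, p("severity.tif"), fm$grid)
      written <- c(written, p("severity.tif"))
    }
    if (is.null(dem)) {
      # no DEM: report already flags planimetric areas
    } else {
      write_raster(fm$weights$slope, p("slope.tif"), fm$grid,
                   type = "Float32")
      write_raster(fm$weights$weight, p("weight.tif"), fm$grid,
                   type = "Float32")
      written <- c(written, p("slope.tif"), p("weight.tif"))
    }
    scr <- screen_indices(pre, post,
                          mask = if (!is.null(aoi)) rasterize_mask(aoi, fm$grid)
                                 else if (inherits(reference, "vector_mask"))
                                   rasterize_mask(reference, fm$grid),
                          wdrvi_a = cfg$wdrvi_a)
    utils::write.csv(scr, p("screening.csv"), row.names = FALSE)
    written <- c(written, p("screening.csv"))
    write_area_report(fm$report, p("report.json"))
    invisible(fm)
  }, error = on_error)
}

#' Screen indices from files
#'
#' @inheritParams run_pipeline
#' @return The screening `data.frame`; also written to
#'   `out_dir/screening.csv` when `out_dir` is configured.
#' @export
screen_pipeline <- function(cfg) {
  cfg <- load_run_config(cfg)
  for (key in c("pre", "post"))
    if (is.null(cfg[[key]])) stop("run config lacks required entry: ", key)
  pre <- read_scene(cfg$pre, band_map = cfg$band_map,
                    scale_factor = cfg$scale_factor)
  post <- read_scene(cfg$post, band_map = cfg$band_map,
                     scale_factor = cfg$scale_factor)
  mask <- NULL
  if (!is.null(cfg$reference) && is.character(cfg$reference) &&
      file.exists(cfg$reference))
    mask <- rasterize_mask(read_vector_mask(cfg$reference,
                                            "reference_delimitation",
                                            crs = pre$grid$crs), pre$grid)
  scr <- screen_indices(pre, post, mask = mask, wdrvi_a = cfg$wdrvi_a)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(scr, file.path(cfg$out_dir, "screening.csv"),
                     row.names = FALSE)
  }
  scr
}

# Normalize a run configuration: accept a list or a flat `key = value` text
# file; fill defaults.
load_run_config <- function(cfg) {
  if (is.character(cfg) && length(cfg) == 1L) {
    lines <- readLines(cfg, warn = FALSE)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    kv <- strsplit(lines, "=", fixed = TRUE)
    cfg <- stats::setNames(
      lapply(kv, function(p) trimws(paste(p[-1], collapse = "="))),
      vapply(kv, function(p) trimws(p[1]), ""))
  }
  stopifnot(is.list(cfg))
  defaults <- list(band_map = superdove_band_map(), scale_factor = 1e-4,
                   index_pair = c("NDVI", "YNDVI"), wdrvi_a = 0.1,
                   seed = 1L, tol = 1e-6, max_iter = 300L,
                   n_trial_bisections = 5L)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (is.character(cfg$index_pair) && length(cfg$index_pair) == 1L)
    cfg$index_pair <- strsplit(cfg$index_pair, ",")[[1]]
  if (is.character(cfg$band_map)) {
    kv <- strsplit(strsplit(cfg$band_map, ",")[[1]], ":")
    cfg$band_map <- stats::setNames(
      vapply(kv, function(p) as.integer(p[2]), 1L),
      vapply(kv, function(p) trimws(p[1]), ""))
  }
  for (nm in c("scale_factor", "wdrvi_a", "tol"))
    cfg[[nm]] <- as.numeric(cfg[[nm]])
  for (nm in c("seed", "max_iter", "n_trial_bisections"))
    cfg[[nm]] <- as.integer(cfg[[nm]])
  cfg$index_pair <- trimws(cfg$index_pair)
  cfg
}
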