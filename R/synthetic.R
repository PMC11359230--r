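# Synthetic paired pre/post scenes with analytic ground truth, so every
# pipeline stage is testable without licensed imagery.

#' Default spectral signatures of the synthetic scenes
#'
#' Mean surface reflectance per band for healthy vegetation and for the four
#' burn-severity levels. Fixture constants chosen to be typical of
#' visible/NIR surface reflectance over Mediterranean vegetation: healthy
#' vegetation has NDVI 0.75, and post-fire NDVI decreases with severity
#' through 0.35, 0.25, 0.15, 0.05 (and YNDVI through 0.33 to 0.03), so the
#' pre-minus-post differences inside the burn span roughly 0.40-0.70 against
#' about 0 outside.
#'
#' @return A list with `healthy` (named numeric vector over
#'   [SUPERDOVE_BANDS]) and `burned` (4 x 8 matrix, one row per severity).
#' @export
default_signatures <- function() {
  bands <- SUPERDOVE_BANDS
  healthy <- c(COASTAL_BLUE = 0.035, BLUE = 0.045, GREEN_I = 0.07,
               GREEN = 0.08, YELLOW = 0.07, RED = 0.06, RED_EDGE = 0.28,
               NIR = 0.42)
  burned <- rbind(
    c(0.050, 0.060, 0.090, 0.100, 0.1360, 0.130, 0.200, 0.270),  # slight
    c(0.055, 0.065, 0.092, 0.102, 0.1565, 0.150, 0.180, 0.250),  # moderate
    c(0.060, 0.070, 0.094, 0.104, 0.1771, 0.170, 0.160, 0.230),  # high
    c(0.065, 0.075, 0.096, 0.106, 0.1978, 0.190, 0.140, 0.210))  # destroyed
  colnames(burned) <- bands
  list(healthy = healthy[bands], burned = burned)
}

# iterated box blur (moving average), replicated edges; separable
smooth_field <- function(m, radius, passes = 3L) {
  k <- 2L * radius + 1L
  blur1d <- function(v) {
    n <- length(v)
    padded <- c(rep(v[1], radius), v, rep(v[n], radius))
    cs <- cumsum(padded)
    (cs[(k):(n + k - 1L)] - c(0, cs[seq_len(n - 1L)])) / k
  }
  for (i in seq_len(passes)) {
    m <- apply(m, 2L, blur1d)
    m <- t(apply(m, 1L, blur1d))
  }
  m
}

# integer distance-to-edge (4-neighbour ring peeling) of TRUE pixels
distance_to_edge <- function(mask) {
  d <- matrix(0L, nrow(mask), ncol(mask))
  current <- mask
  depth <- 0L
  while (any(current)) {
    depth <- depth + 1L
    d[current] <- depth
    nr <- nrow(current); nc <- ncol(current)
    up <- rbind(current[-1, , drop = FALSE], FALSE)
    dn <- rbind(FALSE, current[-nr, , drop = FALSE])
    lf <- cbind(current[, -1, drop = FALSE], FALSE)
    rt <- cbind(FALSE, current[, -nc, drop = FALSE])
    current <- current & up & dn & lf & rt  # erode one ring
  }
  d
}

#' Generate a paired pre/post synthetic fire scene with ground truth
#'
#' The burned region is the top `burned_fraction` quantile of a smoothed
#' random field, so the ground-truth pixel count is exact. It is partitioned
#' into `n_severity_rings` concentric rings by distance-to-edge quantiles
#' (edge = lowest severity, core = destroyed), with exactly equal pixel
#' counts per ring. The pre-fire scene is the healthy signature plus i.i.d.
#' Gaussian reflectance noise; the post-fire scene swaps in the
#' severity-dependent burned signature inside the region, with independent
#' noise. Deterministic for a fixed seed.
#'
#' @param n_rows,n_cols Scene shape (default 300 x 300).
#' @param pixel_size Pixel size in metres (default 3, SuperDove-like).
#' @param burned_fraction Fraction of pixels burned, in (0, 1) (default 0.2).
#' @param n_severity_rings Number of severity rings (default 4).
#' @param noise_sigma Reflectance noise standard deviation (default 0.02).
#' @param seed Integer seed.
#' @param signatures See [default_signatures()].
#' @param origin_x,origin_y,crs Georeferencing of the generated grid.
#' @return List with `pre`, `post` ([scene()]s) and `truth` (list:
#'   `burn_mask` logical matrix, `severity_field` integer matrix 0-3 with
#'   `NA` outside, `true_burned_area_ha` planimetric hectares).
#' @export
simulate_fire_scene <- function(n_rows = 300L, n_cols = 300L, pixel_size = 3,
                                burned_fraction = 0.2, n_severity_rings = 4L,
                                noise_sigma = 0.02, seed = 1L,
                                signatures = default_signatures(),
                                origin_x = 500000, origin_y = 4200000,
                                crs = "EPSG:32634") {
  if (burned_fraction <= 0 || burned_fraction >= 1)
    stop("burned_fraction must lie in (0, 1)")
  n_px <- n_rows * n_cols
  n_burn <- floor(burned_fraction * n_px)
  if (n_burn < n_severity_rings)
    stop("burned_fraction yields fewer pixels than severity rings")
  stopifnot(all(signatures$healthy > 0 & signatures$healthy < 1),
            all(signatures$burned > 0 & signatures$burned < 1),
            nrow(signatures$burned) == n_severity_rings)

  grid <- grid_geometry(n_rows, n_cols, pixel_size, pixel_size,
                        origin_x, origin_y, crs)
  with_seed(seed, {
    field <- smooth_field(matrix(stats::rnorm(n_px), n_rows, n_cols),
                          radius = max(2L, round(min(n_rows, n_cols) / 15)),
                          passes = 3L)
    ord <- order(field, decreasing = TRUE)
    mask <- matrix(FALSE, n_rows, n_cols)
    mask[ord[seq_len(n_burn)]] <- TRUE

    dist <- distance_to_edge(mask)
    sev <- matrix(NA_integer_, n_rows, n_cols)
    burn_idx <- which(mask)
    ring_rank <- order(dist[burn_idx], burn_idx)  # stable: edge first
    per_ring <- diff(round(seq(0, n_burn, length.out = n_severity_rings + 1)))
    sev[burn_idx[ring_rank]] <- rep(seq_len(n_severity_rings) - 1L, per_ring)

    nb <- length(SUPERDOVE_BANDS)
    pre_bands <- vector("list", nb)
    post_bands <- vector("list", nb)
    for (b in seq_len(nb)) {
      base_pre <- matrix(signatures$healthy[b], n_rows, n_cols)
      base_post <- base_pre
      for (k in seq_len(n_severity_rings))
        base_post[!is.na(sev) & sev == k - 1L] <- signatures$burned[k, b]
      pre_bands[[b]] <- base_pre +
        matrix(stats::rnorm(n_px, sd = noise_sigma), n_rows, n_cols)
      post_bands[[b]] <- base_post +
        matrix(stats::rnorm(n_px, sd = noise_sigma), n_rows, n_cols)
    }
    list(pre = scene(pre_bands, grid, superdove_band_map()),
         post = scene(post_bands, grid, superdove_band_map()),
         truth = list(burn_mask = mask, severity_field = sev,
                      true_burned_area_ha = n_burn * pixel_size^2 / 1e4))
  })
}

#' Generate a synthetic DEM with an analytic surface-area factor
#'
#' Produces a coarse DEM (default 30 m, SRTM-like) covering the scene extent
#' plus a margin, together with the exact ratio of true ground surface to
#' planimetric surface: 1 for flat terrain, `1/cos(angle)` for a tilted
#' plane, and a fine numerical quadrature value for the sinusoidal mode.
#'
#' @param scene_grid The scene [grid_geometry()] the DEM must cover.
#' @param mode `"flat"`, `"tilted"` or `"sinusoidal"`.
#' @param angle Tilt angle in degrees (tilted mode), `0 <= angle < 90`;
#'   the plane rises along x.
#' @param amplitude,wavelength Metres (sinusoidal mode, ridges along y).
#' @param pixel_size DEM pixel size in metres (default 30).
#' @param margin_pixels Extra DEM pixels beyond each scene edge (default 3).
#' @return List with `dem` (matrix of elevations, metres), `grid` (DEM
#'   [grid_geometry()]) and `true_area_factor`.
#' @export
simulate_dem <- function(scene_grid, mode = c("flat", "tilted", "sinusoidal"),
                         angle = 30, amplitude = 50, wavelength = 900,
                         pixel_size = 30, margin_pixels = 3L) {
  mode <- match.arg(mode)
  stopifnot(inherits(scene_grid, "grid_geometry"))
  if (mode == "tilted" && (angle < 0 || angle >= 90))
    stop("tilt angle must lie in [0, 90) degrees")

  x0 <- scene_grid$origin_x - margin_pixels * pixel_size
  y0 <- scene_grid$origin_y + margin_pixels * pixel_size
  nc <- ceiling(scene_grid$n_cols * scene_grid$pixel_size_x / pixel_size) +
    2L * margin_pixels
  nr <- ceiling(scene_grid$n_rows * scene_grid$pixel_size_y / pixel_size) +
    2L * margin_pixels
  grid <- grid_geometry(nr, nc, pixel_size, pixel_size, x0, y0,
                        scene_grid$crs)
  ctr <- pixel_centers(grid)
  X <- matrix(ctr$x, nr, nc, byrow = TRUE)

  dem <- switch(mode,
                flat = matrix(0, nr, nc),
                tilted = X * tan(angle * pi / 180),
                sinusoidal = amplitude * sin(2 * pi * X / wavelength))
  factor <- switch(mode,
                   flat = 1,
                   tilted = 1 / cos(angle * pi / 180),
                   sinusoidal = {
                     g <- 2 * pi * amplitude / wavelength
                     stats::integrate(function(t) sqrt(1 + g^2 * cos(t)^2),
                                      0, 2 * pi, rel.tol = 1e-10)$value / (2 * pi)
                   })
  list(dem = dem, grid = grid, true_area_factor = factor)
}
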