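# Shared fixture builders. Everything is generated in code at test time.

# single-pixel (or constant) scene with given reflectances, for scalar
# evaluation of index formulas
scalar_scene <- function(..., n = 1L) {
  refl <- list(...)
  bands <- lapply(refl, function(v) matrix(v, n, n))
  g <- grid_geometry(n, n, 3, 3, 0, n * 3, "EPSG:32634")
  scene(bands, g, stats::setNames(seq_along(refl), names(refl)))
}

# scene pair with a rectangular burned block (rows r1:r2, cols c1:c2) using
# the default signatures at a single severity, for targeted mapping tests
block_scene_pair <- function(nr = 40, nc = 40, r1 = 11, r2 = 25, c1 = 8,
                             c2 = 30, severity = 3L, noise = 0, seed = 1) {
  sig <- default_signatures()
  g <- grid_geometry(nr, nc, 3, 3, 0, nr * 3, "EPSG:32634")
  mask <- matrix(FALSE, nr, nc); mask[r1:r2, c1:c2] <- TRUE
  set.seed(seed)
  mk <- function(sigv) {
    bands <- lapply(seq_along(SUPERDOVE_BANDS), function(b) {
      m <- matrix(sig$healthy[b], nr, nc)
      if (!is.null(sigv)) m[mask] <- sigv[b]
      m + matrix(rnorm(nr * nc, sd = noise), nr, nc)
    })
    scene(bands, g, superdove_band_map())
  }
  list(pre = mk(NULL), post = mk(sig$burned[severity + 1L, ]), mask = mask,
       grid = g)
}

# partition-equality up to label renaming
same_partition <- function(a, b) {
  stopifnot(length(a) == length(b))
  key_a <- match(a, unique(a)); key_b <- match(b, unique(b))
  all(key_a == key_b)
}

tmpfile <- function(ext) tempfile(fileext = ext)
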