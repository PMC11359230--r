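# Expected scalar values below were frozen from independent evaluation of
# each formula (exact fractions where possible, e.g. GEMI(0.5, 0.1) =
# 92881/108900).

test_that("index formulas match independent scalar evaluations", {
  sc <- scalar_scene(NIR = 0.5, RED = 0.1, BLUE = 0.05)
  val <- function(nm, ...) compute_index(sc, nm, ...)$values[1, 1]
  expect_equal(val("NDVI"), 0.4 / 0.6, tolerance = 1e-12)
  expect_equal(val("SR"), 5, tolerance = 1e-12)
  expect_equal(val("SAVI"), 1.5 * 0.4 / 1.1, tolerance = 1e-12)
  expect_equal(val("MSR"), (5 - 1) / (5 + 1), tolerance = 1e-12)
  expect_equal(val("EVI"), 2.5 * 0.4 / (0.5 + 0.6 - 0.375 + 1),
               tolerance = 1e-12)
  expect_equal(val("GEMI"), 92881 / 108900, tolerance = 1e-12)
  expect_equal(val("WDRVI", wdrvi_a = 0.1), (0.05 - 0.1) / (0.05 + 0.1),
               tolerance = 1e-12)

  sc2 <- scalar_scene(NIR = 0.45, YELLOW = 0.09, GREEN_I = 0.09,
                      GREEN = 0.15)
  v2 <- function(nm) compute_index(sc2, nm)$values[1, 1]
  expect_equal(v2("YNDVI"), 0.36 / 0.54, tolerance = 1e-12)
  expect_equal(v2("GNDVI1"), 0.36 / 0.54, tolerance = 1e-12)
  expect_equal(v2("GNDVI2"), 0.30 / 0.60, tolerance = 1e-12)

  expect_equal(compute_index(scalar_scene(NIR = 0.3, RED = 0.3),
                             "NDVI")$values[1, 1], 0)
})

test_that("normalized indices are antisymmetric, bounded and scale invariant", {
  set.seed(11)
  n <- 2000
  a <- runif(n, 1e-4, 1); b <- runif(n, 1e-4, 1)
  nd <- function(x, y) (x - y) / (x + y)
  expect_equal(nd(a, b), -nd(b, a))
  for (f in list(nd, function(x, y) (0.15 * x - y) / (0.15 * x + y))) {
    v <- f(a, b)
    expect_true(all(v >= -1 & v <= 1))
  }
  # through the package surface: random positive reflectance scenes
  g <- grid_geometry(40, 50, 3, 3, 0, 120, "")
  bands <- lapply(1:8, function(i) matrix(runif(2000, 1e-3, 1), 40, 50))
  sc <- scene(bands, g, superdove_band_map())
  for (nm in c("NDVI", "GNDVI1", "GNDVI2", "YNDVI", "MSR", "WDRVI")) {
    v <- compute_index(sc, nm)$values
    expect_true(all(v >= -1 & v <= 1), info = nm)
  }
  expect_true(all(compute_index(sc, "SR")$values >= 0))
  # scale invariance of ratio indices
  sc2 <- scene(lapply(bands, `*`, 0.37), g, superdove_band_map())
  for (nm in c("NDVI", "SR", "MSR", "GNDVI1", "GNDVI2", "YNDVI")) {
    expect_equal(compute_index(sc, nm)$values,
                 compute_index(sc2, nm)$values, tolerance = 1e-12, info = nm)
  }
})

test_that("zero denominators become nodata and band/parameter contracts hold", {
  sc <- scalar_scene(NIR = 0.2, RED = -0.2, n = 2)
  img <- compute_index(sc, "NDVI")
  expect_true(all(img$nodata_mask))
  expect_error(compute_index(sc, "NAVI"), "unknown index")
  expect_error(compute_index(sc, "YNDVI"), "YELLOW")
  expect_error(compute_index(sc, "WDRVI", wdrvi_a = 0.5), "wdrvi_a")
})

test_that("index differencing subtracts, checks names, unions nodata", {
  p <- block_scene_pair(nr = 12, nc = 12, r1 = 4, r2 = 9, c1 = 4, c2 = 9,
                        severity = 3L)
  pre_i <- compute_index(p$pre, "NDVI")
  post_i <- compute_index(p$post, "NDVI")
  d <- index_difference(pre_i, post_i)
  expect_equal(d$values[1, 1], 0, tolerance = 1e-12)        # unburned
  expect_equal(d$values[5, 5], 0.75 - 0.05, tolerance = 1e-12)
  expect_error(index_difference(pre_i, compute_index(p$post, "SR")),
               "distinct indices")
  expect_true(all(index_difference(pre_i, pre_i)$values == 0))

  # nodata union
  pre2 <- pre_i; pre2$nodata_mask[2, 2] <- TRUE
  post2 <- post_i; post2$nodata_mask[3, 3] <- TRUE
  d2 <- index_difference(pre2, post2)
  expect_true(d2$nodata_mask[2, 2] && d2$nodata_mask[3, 3])
  expect_true(is.na(d2$values[2, 2]))
})

test_that("masked mean difference averages valid masked pixels and is linear", {
  p <- block_scene_pair(nr = 10, nc = 10, r1 = 3, r2 = 6, c1 = 3, c2 = 6)
  d <- index_difference(compute_index(p$pre, "NDVI"),
                        compute_index(p$post, "NDVI"))
  inside <- masked_mean_difference(d, p$mask)
  outside <- masked_mean_difference(d, !p$mask)
  expect_equal(inside, 0.70, tolerance = 1e-12)
  expect_equal(outside, 0, tolerance = 1e-12)
  expect_gt(inside, outside)

  d3 <- d; d3$values <- 3 * d$values
  expect_equal(masked_mean_difference(d3, p$mask), 3 * inside,
               tolerance = 1e-12)
  # two-point mean
  d$values[] <- NA; d$nodata_mask[] <- TRUE
  d$values[1, 1] <- 0.2; d$values[1, 2] <- 0.4
  d$nodata_mask[1, 1:2] <- FALSE
  expect_equal(masked_mean_difference(d, matrix(TRUE, 10, 10)), 0.3)
  expect_error(masked_mean_difference(d, matrix(FALSE, 10, 10)),
               "no valid pixels")
})

test_that("index screening ranks ratio indices on a burn and flags missing bands", {
  p <- block_scene_pair(nr = 30, nc = 30, r1 = 8, r2 = 22, c1 = 8, c2 = 22,
                        severity = 2L, noise = 0.005, seed = 3)
  scr <- screen_indices(p$pre, p$post, p$mask)
  expect_equal(nrow(scr), 10)
  expect_identical(scr$index_name[1], "SR")
  expect_true("MSR" %in% scr$index_name[1:3])
  expect_true(all(diff(scr$mean_difference) <= 0))
  expect_true(all(scr$n_pixels == sum(p$mask)))

  # identical scenes: all means zero
  scr0 <- screen_indices(p$pre, p$pre, p$mask)
  expect_true(all(abs(scr0$mean_difference) < 1e-12))

  # no YELLOW band: YNDVI omitted with a warning
  bm <- superdove_band_map()[setdiff(SUPERDOVE_BANDS, "YELLOW")]
  pre2 <- scene(p$pre$bands, p$grid, bm)
  post2 <- scene(p$post$bands, p$grid, bm)
  expect_warning(scr2 <- screen_indices(pre2, post2, p$mask), "YNDVI")
  expect_false("YNDVI" %in% scr2$index_name)
  expect_equal(nrow(scr2), 9)
})
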