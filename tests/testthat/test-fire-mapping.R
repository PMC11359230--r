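diff_pair <- function(sim) {
  list(index_difference(compute_index(sim$pre, "NDVI"),
                        compute_index(sim$post, "NDVI")),
       index_difference(compute_index(sim$pre, "YNDVI"),
                        compute_index(sim$post, "YNDVI")))
}

test_that("burned-cluster labelling follows combined index loss", {
  fake <- function(centers) structure(list(centers = centers, K = 2L),
                                      class = "cluster_result")
  expect_equal(label_burned_cluster(fake(rbind(c(0.5, 0.4), c(0.02, 0.01)))), 0L)
  expect_equal(label_burned_cluster(fake(rbind(c(0.02, 0.01), c(0.5, 0.4)))), 1L)
  # tie on the sum: larger first coordinate wins
  expect_equal(label_burned_cluster(fake(rbind(c(0.3, 0.1), c(0.1, 0.3)))), 0L)
  expect_equal(label_burned_cluster(fake(rbind(c(0.1, 0.3), c(0.3, 0.1)))), 1L)
  expect_warning(out <- label_burned_cluster(fake(rbind(c(0.2, 0.2),
                                                        c(0.2, 0.2)))),
                 "coincide")
  expect_equal(out, 0L)
})

test_that("burned area is recovered on a noisy synthetic scene", {
  sim <- simulate_fire_scene(n_rows = 80, n_cols = 80, noise_sigma = 0.02,
                             seed = 17)
  d <- diff_pair(sim)
  out <- map_burned_area(d[[1]], d[[2]], seed = 17)
  acc <- mean(out$mask$values == sim$truth$burn_mask)
  expect_gte(acc, 0.99)
  expect_equal(out$mask$n_burned, sum(out$mask$values, na.rm = TRUE))
  # the burned cluster contains the ground-truth burn centroid
  burned_id <- label_burned_cluster(out$clustering)
  truth_centroid <- c(mean(d[[1]]$values[sim$truth$burn_mask]),
                      mean(d[[2]]$values[sim$truth$burn_mask]))
  d2 <- colSums((t(out$clustering$centers) - truth_centroid)^2)
  expect_equal(which.min(d2) - 1L, burned_id)
})

test_that("burned and unburned pixels partition the valid pixels", {
  sim <- simulate_fire_scene(n_rows = 50, n_cols = 50, seed = 3)
  d <- diff_pair(sim)
  out <- map_burned_area(d[[1]], d[[2]], seed = 3)
  valid <- !d[[1]]$nodata_mask & !d[[2]]$nodata_mask
  expect_true(all(!is.na(out$mask$values[valid])))
  expect_true(all(is.na(out$mask$values[!valid])))
})

test_that("constant difference images give a flagged no-burn result", {
  g <- grid_geometry(10, 10, 3, 3, 0, 30, "")
  mk <- function(v) structure(list(values = matrix(v, 10, 10),
                                   index_name = "NDVI",
                                   nodata_mask = matrix(FALSE, 10, 10),
                                   grid = g), class = "difference_image")
  expect_warning(out <- map_burned_area(mk(0.3), mk(0.3)), "constant")
  expect_equal(out$mask$n_burned, 0L)
  expect_true("low_separation" %in% out$mask$flags)
})

test_that("pure-noise differences are flagged as below the noise floor", {
  sim <- simulate_fire_scene(n_rows = 40, n_cols = 40, seed = 5)
  d0 <- index_difference(compute_index(sim$pre, "NDVI"),
                         compute_index(sim$pre, "NDVI"))
  d0$values <- matrix(rnorm(1600, sd = 1e-3), 40, 40)
  d0y <- d0; d0y$index_name <- "YNDVI"
  d0y$values <- matrix(rnorm(1600, sd = 1e-3), 40, 40)
  expect_warning(out <- map_burned_area(d0, d0y, seed = 5), "unreliable")
  expect_true("low_separation" %in% out$mask$flags)
})

test_that("an AOI restricts the analysis consistently", {
  sim <- simulate_fire_scene(n_rows = 60, n_cols = 60, noise_sigma = 0,
                             seed = 11)
  d <- diff_pair(sim)
  full <- map_burned_area(d[[1]], d[[2]], seed = 11)
  rows <- range(which(rowSums(sim$truth$burn_mask) > 0))
  cols <- range(which(colSums(sim$truth$burn_mask) > 0))
  aoi <- matrix(FALSE, 60, 60)
  aoi[rows[1]:rows[2], cols[1]:cols[2]] <- TRUE
  sub <- map_burned_area(d[[1]], d[[2]], aoi = aoi, seed = 11)
  expect_true(all(is.na(sub$mask$values[!aoi])))
  expect_equal(sub$mask$values[aoi], full$mask$values[aoi])
})

test_that("severity classes are ordered by burn intensity and contained in the mask", {
  sim <- simulate_fire_scene(n_rows = 60, n_cols = 60, noise_sigma = 0,
                             seed = 23)
  d <- diff_pair(sim)
  burn <- map_burned_area(d[[1]], d[[2]], seed = 23)
  out <- map_severity(d[[1]], d[[2]], burn$mask, seed = 23)
  sev <- out$severity
  expect_false(is.null(sev))
  # containment: labelled pixels are exactly the burned pixels
  expect_identical(!is.na(sev$values),
                   !is.na(burn$mask$values) & burn$mask$values)
  # conservation: class counts sum to n_burned; shares to 100%
  expect_equal(sum(sev$class_counts), burn$mask$n_burned)
  expect_equal(sum(severity_percentages(sev)), 100, tolerance = 1e-9)
  # noiseless recovery: class equals ground-truth ring everywhere
  both <- !is.na(sev$values) & !is.na(sim$truth$severity_field)
  expect_gte(mean(both[!is.na(sev$values)]), 0.99)
  expect_equal(sev$values[both], sim$truth$severity_field[both])
  expect_equal(cor(as.numeric(sev$values[both]),
                   as.numeric(sim$truth$severity_field[both]),
                   method = "spearman"), 1)
})

test_that("severity handles degenerate and tiny inputs", {
  g <- grid_geometry(6, 6, 3, 3, 0, 18, "")
  mk <- function(v) structure(list(values = v, index_name = "NDVI",
                                   nodata_mask = matrix(FALSE, 6, 6),
                                   grid = g), class = "difference_image")
  vals <- matrix(0, 6, 6); vals[1:3, 1:4] <- 0.5
  mask_vals <- matrix(FALSE, 6, 6); mask_vals[1:3, 1:4] <- TRUE
  mask <- structure(list(values = mask_vals, grid = g, n_burned = 12L,
                         flags = character(0)), class = "burn_mask")
  # identical features on all burned pixels: repair kicks in, flag raised
  out <- map_severity(mk(vals), mk(vals), mask, seed = 1)
  expect_true("degenerate" %in% out$severity$flags)
  expect_equal(sum(out$severity$class_counts), 12)

  small <- mask; small$values[] <- FALSE; small$values[1, 1:3] <- TRUE
  small$n_burned <- 3L
  expect_warning(res <- map_severity(mk(vals), mk(vals), small, seed = 1),
                 "fewer than 4")
  expect_null(res$severity)
})

test_that("classification accuracy does not degrade as noise falls", {
  accs <- vapply(c(0.1, 0.05, 0.02), function(sg) {
    sim <- simulate_fire_scene(n_rows = 70, n_cols = 70, noise_sigma = sg,
                               seed = 29)
    d <- diff_pair(sim)
    out <- suppressWarnings(map_burned_area(d[[1]], d[[2]], seed = 29))
    mean(out$mask$values == sim$truth$burn_mask)
  }, 1)
  expect_true(all(diff(accs) >= 0))
  expect_gte(accs[3], 0.99)
})
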