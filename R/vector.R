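#' Construct a vector mask from polygon rings
#'
#' A vector mask is one or more polygons (outer ring plus optional hole
#' rings) in the scene CRS, used either as an area of interest or as a
#' reference burned-area delimitation to compare against.
#'
#' @param polygons A list of polygons; each polygon is a list of rings, each
#'   ring a two-column matrix of x/y vertices. Rings are closed automatically
#'   if the last vertex differs from the first, and validated to be
#'   non-self-intersecting.
#' @param role `"aoi"` or `"reference_delimitation"`.
#' @param crs CRS identifier the coordinates are expressed in (may be `""`).
#' @return An object of class `vector_mask`.
#' @export
vector_mask <- function(polygons, role = c("aoi", "reference_delimitation"),
                        crs = "") {
  role <- match.arg(role)
  if (!length(polygons)) stop("empty polygon set")
  polygons <- lapply(polygons, function(poly) {
    if (is.matrix(poly)) poly <- list(poly)
    lapply(poly, function(ring) {
      ring <- as.matrix(ring)
      if (ncol(ring) < 2) stop("polygon rings need x and y columns")
      ring <- ring[, 1:2, drop = FALSE]
      storage.mode(ring) <- "double"
      if (nrow(ring) < 3) stop("polygon rings need at least 3 vertices")
      if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
      if (nrow(ring) < 4) stop("polygon rings need at least 3 distinct vertices")
      if (ring_self_intersects(ring)) stop("self-intersecting polygon ring")
      ring
    })
  })
  structure(list(polygons = polygons, role = role, crs = as.character(crs)),
            class = "vector_mask")
}

# Even-odd validity check: any two non-adjacent edges of a closed ring must
# not cross. O(m^2); rings in practice are small.
ring_self_intersects <- function(ring) {
  m <- nrow(ring) - 1L  # edges
  if (m < 4L) return(FALSE)
  seg <- function(i) list(p = ring[i, ], q = ring[i + 1L, ])
  cross <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  for (i in seq_len(m - 2L)) {
    jmax <- if (i == 1L) m - 1L else m
    for (j in seq.int(i + 2L, jmax)) {
      s1 <- seg(i); s2 <- seg(j)
      d1 <- cross(s2$p, s2$q, s1$p); d2 <- cross(s2$p, s2$q, s1$q)
      d3 <- cross(s1$p, s1$q, s2$p); d4 <- cross(s1$p, s1$q, s2$q)
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Read a vector mask from GeoJSON
#'
#' Accepts a `Polygon` or `MultiPolygon` geometry, a `Feature`, or a
#' `FeatureCollection` of such features.
#'
#' @param path Path to a GeoJSON file.
#' @param role `"aoi"` or `"reference_delimitation"`.
#' @param crs CRS the coordinates are taken to be in (GeoJSON itself does not
#'   carry projected CRS metadata; the caller declares it).
#' @return A [vector_mask()].
#' @export
read_vector_mask <- function(path, role = c("aoi", "reference_delimitation"),
                             crs = "") {
  role <- match.arg(role)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  geoms <- switch(gj$type %||% stop("not a GeoJSON object"),
                  FeatureCollection = lapply(gj$features, `[[`, "geometry"),
                  Feature = list(gj$geometry),
                  Polygon = , MultiPolygon = list(gj),
                  stop("unsupported GeoJSON type: ", gj$type))
  polygons <- list()
  for (g in geoms) {
    ring_mat <- function(ring)
      do.call(rbind, lapply(ring, function(pt) as.numeric(pt[1:2])))
    if (g$type == "Polygon") {
      polygons <- c(polygons, list(lapply(g$coordinates, ring_mat)))
    } else if (g$type == "MultiPolygon") {
      polygons <- c(polygons,
                    lapply(g$coordinates, function(p) lapply(p, ring_mat)))
    } else stop("unsupported geometry type: ", g$type)
  }
  vector_mask(polygons, role = role, crs = crs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rasterize a vector mask onto a grid
#'
#' A pixel is `TRUE` iff its centre lies inside any polygon
#' (centre-containment rule, even-odd so hole rings are excluded). The mask
#' CRS must equal the grid CRS; reprojection is the caller's duty.
#'
#' @param mask A [vector_mask()].
#' @param grid A [grid_geometry()].
#' @return Logical matrix of the grid shape.
#' @export
rasterize_mask <- function(mask, grid) {
  stopifnot(inherits(mask, "vector_mask"), inherits(grid, "grid_geometry"))
  if (nzchar(mask$crs) && nzchar(grid$crs) &&
      !identical(toupper(mask$crs), toupper(grid$crs)))
    stop(sprintf("vector mask CRS (%s) differs from grid CRS (%s); reproject first",
                 mask$crs, grid$crs))
  ctr <- pixel_centers(grid)
  pts <- cbind(rep(ctr$x, each = grid$n_rows),
               rep(ctr$y, times = grid$n_cols))
  out <- rep(FALSE, nrow(pts))
  for (poly in mask$polygons) {
    bnd <- do.call(rbind, lapply(poly, function(r) rbind(r, c(NA, NA))))
    bnd <- bnd[-nrow(bnd), , drop = FALSE]
    out <- out | mgcv::in.out(bnd, pts)
  }
  matrix(out, grid$n_rows, grid$n_cols)
}
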