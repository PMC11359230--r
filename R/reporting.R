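#' Discrepancy between an estimated and a reference burned area
#'
#' Signed difference `reference - estimated` in hectares, and the percentage
#' of the reference area it represents (the convention that reproduces
#' published burned-area comparisons against reference delimitations).
#'
#' @param estimated_ha Estimated burned area, hectares.
#' @param reference_ha Reference (delimitation) area, hectares; must be > 0.
#' @return List with `difference_ha` and `difference_pct`, both rounded to
#'   2 decimals, plus unrounded `difference_ha_raw`, `difference_pct_raw`.
#' @export
area_discrepancy <- function(estimated_ha, reference_ha) {
  if (!is.numeric(reference_ha) || reference_ha <= 0)
    stop("reference area must be positive")
  diff <- reference_ha - estimated_ha
  pct <- 100 * diff / reference_ha
  list(difference_ha = round(diff, 2), difference_pct = round(pct, 2),
       difference_ha_raw = diff, difference_pct_raw = pct)
}

#' Severity-class shares of the burned surface
#'
#' Per-class slope-weighted surface divided by the total burned surface,
#' times 100. Surface-weighted shares are consistent with the area pipeline;
#' on flat terrain they reduce to pixel shares.
#'
#' @param sev A `severity_map` from [map_severity()].
#' @param weights Optional [slope_weights()] on the same grid.
#' @return Numeric vector of 4 percentages (unrounded; they sum to 100).
#' @export
severity_percentages <- function(sev, weights = NULL) {
  stopifnot(inherits(sev, "severity_map"))
  if (sum(sev$class_counts) == 0L) stop("empty severity map")
  w <- if (is.null(weights)) matrix(1, sev$grid$n_rows, sev$grid$n_cols)
       else {
         stopifnot(inherits(weights, "slope_weights"))
         check_same_grid(sev$grid, weights$grid, "severity map and weights")
         weights$weight
       }
  surf <- vapply(0:3, function(k)
    sum(w[!is.na(sev$values) & sev$values == k]), 1)
  100 * surf / sum(surf)
}

#' Surface area of a reference delimitation polygon, in hectares
#'
#' Rasterizes the polygon onto the scene grid (centre containment) and sums
#' pixel surfaces with the same slope weighting as the estimate, so both
#' sides of a comparison use one area definition.
#'
#' @param mask A [vector_mask()].
#' @param grid Scene [grid_geometry()].
#' @param weights Optional [slope_weights()].
#' @return Hectares.
#' @export
reference_area_from_mask <- function(mask, grid, weights = NULL) {
  plane <- rasterize_mask(mask, grid)
  if (!any(plane)) stop("reference polygon does not intersect the grid")
  weighted_area(plane, weights = weights, grid = grid)
}

#' Assemble the quantitative area/severity report
#'
#' @param estimated_burned_ha Slope-weighted burned hectares.
#' @param reference_ha Reference delimitation hectares, or `NULL`.
#' @param severity_pct Numeric vector of 4 severity percentages, or `NULL`.
#' @param flags Character vector of warning flags accumulated by the run.
#' @param diagnostics Optional list (cluster centroids, SSEs, seeds, ...).
#' @return An object of class `area_report`.
#' @export
area_report <- function(estimated_burned_ha, reference_ha = NULL,
                        severity_pct = NULL, flags = character(0),
                        diagnostics = NULL) {
  rep <- list(estimated_burned_ha = estimated_burned_ha,
              reference_ha = reference_ha,
              difference_ha = NULL, difference_pct = NULL,
              severity_labels = SEVERITY_LABELS,
              severity_pct = severity_pct,
              severity_pct_display = if (!is.null(severity_pct))
                round(severity_pct) else NULL,
              flags = flags, diagnostics = diagnostics)
  if (!is.null(reference_ha)) {
    d <- area_discrepancy(estimated_burned_ha, reference_ha)
    rep$difference_ha <- d$difference_ha
    rep$difference_pct <- d$difference_pct
  }
  structure(rep, class = "area_report")
}

#' @export
print.area_report <- function(x, ...) {
  cat("Burned-area report\n")
  cat(sprintf("  estimated burned surface: %.2f ha\n", x$estimated_burned_ha))
  if (!is.null(x$reference_ha))
    cat(sprintf("  reference delimitation:   %.2f ha  (difference %.2f ha, %.2f%% of reference)\n",
                x$reference_ha, x$difference_ha, x$difference_pct))
  if (!is.null(x$severity_pct)) {
    cat("  severity shares of burned surface:\n")
    for (k in 1:4)
      cat(sprintf("    %-28s %3d%%\n", x$severity_labels[k],
                  x$severity_pct_display[k]))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Write a report as JSON
#'
#' Numbers are serialized at full precision so that a write/read round trip
#' preserves every numeric field exactly; output is byte-stable for identical
#' inputs.
#'
#' @param report An [area_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_area_report <- function(report, path) {
  stopifnot(inherits(report, "area_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a JSON report back
#'
#' @param path Path written by [write_area_report()].
#' @return An [area_report()].
#' @export
read_area_report <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  x$flags <- as.character(x$flags)
  structure(x, class = "area_report")
}
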