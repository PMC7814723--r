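#' Friction and travel time directly from a scene
#'
#' Convenience wrappers tying the pipeline together: `scene_friction()`
#' rasterizes the scene's roads and compiles the friction surface for one
#' scenario; `scene_travel_time()` additionally selects the eligible
#' facilities for a tier level and runs the shortest-path solver.
#'
#' @param scene A `synthetic_scene` (or any list with the same layers).
#' @param scenario A [scenario_spec()].
#' @param level Facility tier in [facility_levels].
#' @param road_raster Optional pre-rasterized roads, to avoid recomputing
#'   across scenarios.
#' @return `scene_friction()`: a `friction_surface`;
#'   `scene_travel_time()`: a `travel_time_surface`.
#' @export
scene_friction <- function(scene, scenario, road_raster = NULL) {
  if (is.null(road_raster)) road_raster <- rasterize_roads(scene$roads,
                                                           scene$grid)
  build_friction(scene$landcover, road_raster, scene$barriers, scenario,
                 scene$grid, mask = scene$study_mask)
}

#' @rdname scene_friction
#' @export
scene_travel_time <- function(scene, level, scenario, road_raster = NULL) {
  fr <- scene_friction(scene, scenario, road_raster)
  el <- eligible_facilities(scene$facilities, level)
  compute_travel_time(fr, el, level = level)
}

#' Proportion of population within a travel-time threshold
#'
#' Sums population over cells whose travel time is at or below the threshold
#' (closed comparison: exactly-on-threshold cells count), divided by the
#' total population of the study area. Population on unreachable or
#' impassable cells stays in the denominator — coverage is a share of the
#' whole population.
#'
#' @param tt A `travel_time_surface`.
#' @param pop Population-count matrix on the same grid.
#' @param threshold Minutes (default 60).
#' @param mask Optional logical study mask for the denominator.
#' @return A proportion in [0, 1].
#' @export
population_within <- function(tt, pop, threshold = 60, mask = NULL) {
  stopifnot(all(dim(pop) == dim(tt$minutes)))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(pop), ncol(pop))
  total <- sum(pop[mask])
  if (total <= 0) stop("zero total population")
  covered <- tt$minutes <= threshold & mask
  sum(pop[covered]) / total
}

#' Coverage table across tiers, modes and speed multipliers
#'
#' For every tier level and transport mode, computes the proportion of the
#' population within `threshold` minutes of the nearest eligible facility at
#' the central speed multiplier, plus a (low, high) interval from the -20%
#' and +20% speed variants.
#'
#' @param scene A `synthetic_scene`.
#' @param levels Tier levels (default all six).
#' @param modes Transport modes (default walk, bicycle, drive).
#' @param multipliers Numeric c(low, central, high); default
#'   `c(0.8, 1, 1.2)`.
#' @param threshold Minutes (default 60).
#' @return Data frame of class `coverage_table` with columns `level`,
#'   `mode`, `coverage`, `low`, `high` (proportions in [0, 1]).
#' @export
coverage_matrix <- function(scene, levels = facility_levels,
                            modes = c("walk", "bicycle", "drive"),
                            multipliers = c(0.8, 1, 1.2),
                            threshold = 60) {
  stopifnot(length(multipliers) == 3L)
  road_raster <- rasterize_roads(scene$roads, scene$grid)
  rows <- list()
  for (mode in modes) {
    for (level in levels) {
      vals <- vapply(multipliers, function(m) {
        tt <- scene_travel_time(scene, level,
                                scenario_spec(mode, multiplier = m),
                                road_raster)
        population_within(tt, scene$population, threshold,
                          scene$study_mask)
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        level = level, mode = mode,
        coverage = vals[2L], low = vals[1L], high = vals[3L])
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- threshold
  class(out) <- c("coverage_table", "data.frame")
  out
}

#' Percentage-point difference between two coverages
#'
#' @param cov_a,cov_b Coverages, either both proportions in [0, 1]
#'   (default) or both already percentages.
#' @param units `"proportion"` or `"percent"`; mixing units is an error, so
#'   the caller must say which scale both inputs share.
#' @return Percentage points, `cov_b - cov_a`.
#' @export
percentage_point_gain <- function(cov_a, cov_b,
                                  units = c("proportion", "percent")) {
  units <- match.arg(units)
  if (units == "proportion") {
    if (any(c(cov_a, cov_b) > 1) || any(c(cov_a, cov_b) < 0))
      stop("inputs declared as proportions must lie in [0, 1]; ",
           "use units = 'percent' for percentage inputs")
    100 * (cov_b - cov_a)
  } else {
    cov_b - cov_a
  }
}

#' Write a coverage table as CSV
#'
#' Central value with the parenthesized low-high interval, one row per
#' tier level and mode, percentages to two decimals.
#'
#' @param cov A `coverage_table`.
#' @param path Output CSV path.
#' @export
write_coverage_csv <- function(cov, path) {
  fmt <- function(c0, lo, hi)
    sprintf("%.2f%% (%.2f-%.2f)", 100 * c0, 100 * lo, 100 * hi)
  wide <- stats::reshape(
    transform(cov[, c("level", "mode")],
              cell = fmt(cov$coverage, cov$low, cov$high)),
    idvar = "level", timevar = "mode", direction = "wide")
  names(wide) <- sub("^cell\\.", "", names(wide))
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}
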