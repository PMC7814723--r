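#' Health-facility tier levels
#'
#' The six-tier hierarchy, ordered from lowest to highest: Health Center II,
#' Health Center III, Health Center IV, General Hospital, Regional Referral
#' Hospital, National Referral Hospital. A level-L analysis admits all
#' facilities of tier L and above, because any service offered at level L is
#' also offered higher up the referral chain.
#'
#' @export
facility_levels <- c("HC2", "HC3", "HC4", "GH", "RRH", "NRH")

#' Construct a facility set
#'
#' @param x,y Planar coordinates of facility points.
#' @param level Character or factor of tiers in [facility_levels].
#' @return Data frame with columns `x`, `y`, `level` (ordered factor),
#'   class `facility_set`.
#' @export
facility_set <- function(x, y, level) {
  if (length(x) == 0L) stop("at least one facility is required")
  level <- factor(as.character(level), levels = facility_levels,
                  ordered = TRUE)
  if (anyNA(level)) stop("unknown facility level")
  structure(data.frame(x = x, y = y, level = level),
            class = c("facility_set", "data.frame"))
}

#' Facilities eligible for a tier-level analysis
#'
#' Returns every facility whose tier is at or above `level`: higher-level
#' facilities are included in lower-level analyses.
#'
#' @param facilities A [facility_set()].
#' @param level A tier in [facility_levels].
#' @return A [facility_set()] subset.
#' @export
eligible_facilities <- function(facilities, level) {
  level <- match.arg(level, facility_levels)
  keep <- as.integer(facilities$level) >=
    match(level, facility_levels)
  out <- facilities[keep, , drop = FALSE]
  class(out) <- c("facility_set", "data.frame")
  out
}

# Snap facilities to passable cells. A facility whose cell is impassable
# moves to the nearest passable cell (cell-center Euclidean distance,
# deterministic row-major tie-break) within `radius` cells, else errors.
snap_facilities <- function(facilities, friction, radius = 3L) {
  grid <- friction$grid
  rc <- point_to_cell(grid, facilities$x, facilities$y)
  if (anyNA(rc)) stop("facility outside the grid extent")
  for (i in seq_len(nrow(rc))) {
    r <- rc[i, 1L]; c <- rc[i, 2L]
    if (friction$passable[r, c]) next
    best <- NULL; best_d <- Inf
    for (dr in -radius:radius) for (dc in -radius:radius) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1L || r2 > grid$nrows || c2 < 1L || c2 > grid$ncols) next
      if (!friction$passable[r2, c2]) next
      d <- dr * dr + dc * dc
      if (d < best_d) { best_d <- d; best <- c(r2, c2) }
    }
    if (is.null(best))
      stop(sprintf("facility %d has no passable cell within %d cells",
                   i, radius))
    rc[i, ] <- best
  }
  rc
}

#' Travel time to the nearest eligible facility
#'
#' Exact multi-source Dijkstra over the 8-connected grid graph of the
#' friction surface. The cost of moving between adjacent cells a and b is
#' half the step length at each cell's speed, `t = (d/2)/v_a + (d/2)/v_b`,
#' with `d` the cell size (orthogonal) or `cell_size * sqrt(2)` (diagonal).
#' Facility cells get time 0; cells disconnected from every facility get
#' `+Inf`.
#'
#' @param friction A `friction_surface` from [build_friction()].
#' @param sources A [facility_set()]; facilities on impassable cells snap to
#'   the nearest passable cell within `snap_radius` cells.
#' @param level Optional tier recorded in the provenance (the caller is
#'   expected to have applied [eligible_facilities()] already).
#' @param snap_radius Snapping search radius in cells (default 3).
#' @return A `travel_time_surface`: list with `grid`, `minutes` matrix
#'   (`+Inf` where unreachable) and `provenance` (level, mode, multiplier).
#' @export
compute_travel_time <- function(friction, sources, level = NA_character_,
                                snap_radius = 3L) {
  if (is.null(sources) || nrow(sources) == 0L) stop("empty source set")
  rc <- snap_facilities(sources, friction, radius = snap_radius)
  minutes <- .grid_dijkstra(friction$speed, friction$grid$cell_size, rc)
  structure(list(grid = friction$grid, minutes = minutes,
                 provenance = list(level = level,
                                   mode = friction$scenario$mode,
                                   multiplier = friction$scenario$multiplier)),
            class = "travel_time_surface")
}

#' @export
print.travel_time_surface <- function(x, ...) {
  fin <- is.finite(x$minutes)
  cat(sprintf(
    "<travel_time_surface> level %s, %s, multiplier %g; median %.1f min, %d unreachable cells\n",
    x$provenance$level, x$provenance$mode, x$provenance$multiplier,
    stats::median(x$minutes[fin]), sum(!fin)))
  invisible(x)
}

#' Minutes saved by bicycling instead of walking
#'
#' Cell-wise walking minus bicycling travel time, for two surfaces computed
#' to the same facility level at the same speed multiplier. Cells
#' unreachable under both modes are `NA`; cells unreachable on foot but
#' reachable by bicycle are `+Inf` (capped no-data, flagged).
#'
#' @param walk,bike `travel_time_surface` objects sharing grid, level and
#'   multiplier.
#' @return Numeric matrix of minutes saved.
#' @export
time_saved <- function(walk, bike) {
  check_same_grid(walk$grid, bike$grid)
  pw <- walk$provenance; pb <- bike$provenance
  if (!identical(pw$level, pb$level) ||
      !identical(pw$multiplier, pb$multiplier))
    stop("mismatched provenance: surfaces must share level and multiplier")
  saved <- walk$minutes - bike$minutes
  both_un <- !is.finite(walk$minutes) & !is.finite(bike$minutes)
  saved[both_un] <- NA_real_
  only_walk_un <- !is.finite(walk$minutes) & is.finite(bike$minutes)
  saved[only_walk_un] <- Inf
  saved
}
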