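#' Landcover classes used by the friction model
#'
#' Nine landcover classes plus three road classes. The landcover raster holds
#' integer codes 1-9 (column `code`); road classes live in a separate
#' rasterized-road layer (codes 1 = primary, 2 = secondary, 3 = tertiary).
#'
#' @format Data frame with columns `code` and `name`.
#' @export
landcover_classes <- data.frame(
  code = 1:9,
  name = c("forests", "shrublands", "grassland", "cropland", "flooded",
           "sparse_vegetation", "bare_areas", "built_up", "open_water"),
  stringsAsFactors = FALSE
)

road_class_names <- c("primary_road", "secondary_road", "tertiary_road")

#' Default mode speed tables
#'
#' Reads the speed tables shipped with the package (km/h per class for the
#' walking, bicycling and driving scenarios). Water and regularly flooded
#' areas carry speed 0 and are treated as impassable.
#'
#' @param path Optional path to a YAML file with the same layout, to supply
#'   custom tables.
#' @return Named list of named numeric vectors, one per mode.
#' @export
default_speed_tables <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "speed_tables.yaml", package = "hfaccess")
  }
  tabs <- yaml::read_yaml(path)
  lapply(tabs, function(t) unlist(t))
}

#' Specify a travel scenario
#'
#' A scenario is a transport mode, a class-to-speed table and a speed
#' multiplier. The multiplier scales every speed uniformly; 0.8 and 1.2 give
#' the -20%/+20% uncertainty variants around the central run at 1.0.
#'
#' @param mode One of `"walk"`, `"bicycle"`, `"drive"`.
#' @param multiplier Positive speed multiplier (default 1).
#' @param speed_table Named speed vector (km/h); defaults to the shipped
#'   table for `mode`.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(mode = c("walk", "bicycle", "drive"),
                          multiplier = 1,
                          speed_table = NULL) {
  mode <- match.arg(mode)
  if (is.null(speed_table)) speed_table <- default_speed_tables()[[mode]]
  if (any(speed_table < 0)) stop("speeds must be >= 0")
  if (!is.numeric(multiplier) || length(multiplier) != 1L || multiplier <= 0)
    stop("multiplier must be a single positive number")
  structure(list(mode = mode, multiplier = multiplier,
                 speed_table = speed_table),
            class = "scenario_spec")
}

# Supercover grid traversal of one segment in unit cell coordinates.
# Returns every cell the segment passes through; at exact corner crossings
# both corner-adjacent cells are added so the rasterized line never lets an
# 8-connected path slip through a diagonal gap.
supercover_segment <- function(grid, x0, y0, x1, y1) {
  cs <- grid$cell_size
  eps <- 1e-9
  u0 <- (x0 - grid$origin[1]) / cs; v0 <- (y0 - grid$origin[2]) / cs
  u1 <- (x1 - grid$origin[1]) / cs; v1 <- (y1 - grid$origin[2]) / cs
  # nudge endpoints off exact grid lines for a stable traversal
  nudge <- function(a) ifelse(abs(a - round(a)) < eps, a + 2 * eps, a)
  u0 <- nudge(u0); v0 <- nudge(v0); u1 <- nudge(u1); v1 <- nudge(v1)
  du <- u1 - u0; dv <- v1 - v0
  cx <- floor(u0); cy <- floor(v0)
  ex <- floor(u1); ey <- floor(v1)
  sx <- sign(du); sy <- sign(dv)
  tdx <- if (du != 0) abs(1 / du) else Inf
  tdy <- if (dv != 0) abs(1 / dv) else Inf
  tmx <- if (du != 0) ((cx + (sx > 0)) - u0) / du else Inf
  tmy <- if (dv != 0) ((cy + (sy > 0)) - v0) / dv else Inf
  out <- matrix(NA_integer_, nrow = 4L * (abs(ex - cx) + abs(ey - cy) + 2L),
                ncol = 2L)
  n <- 0L
  push <- function(x, y) {
    n <<- n + 1L
    out[n, ] <<- c(x, y)
  }
  push(cx, cy)
  it <- 0L
  while ((cx != ex || cy != ey) && it < 4L * (grid$nrows + grid$ncols)) {
    it <- it + 1L
    if (abs(tmx - tmy) < eps && is.finite(tmx)) {
      push(cx + sx, cy); push(cx, cy + sy)      # corner: both side cells
      cx <- cx + sx; cy <- cy + sy
      tmx <- tmx + tdx; tmy <- tmy + tdy
    } else if (tmx < tmy) {
      cx <- cx + sx; tmx <- tmx + tdx
    } else {
      cy <- cy + sy; tmy <- tmy + tdy
    }
    push(cx, cy)
  }
  out <- out[seq_len(n), , drop = FALSE]
  # unit coords are 0-based from the lower-left; convert to (row, col)
  row <- grid$nrows - out[, 2L]
  col <- out[, 1L] + 1L
  keep <- row >= 1L & row <= grid$nrows & col >= 1L & col <= grid$ncols
  cbind(row = row[keep], col = col[keep])
}

#' Rasterize classed road polylines
#'
#' Burns road segments into a categorical raster using a supercover line
#' traversal (every cell the segment touches is marked, with both cells kept
#' at exact corner crossings). Where road classes overlap in one cell the
#' highest-priority class wins: primary > secondary > tertiary.
#'
#' @param roads Data frame of segments with columns `x0, y0, x1, y1, class`;
#'   `class` must be one of `"primary"`, `"secondary"`, `"tertiary"`.
#' @param grid A [grid_spec()].
#' @return Integer matrix; 0 = no road, 1 = primary, 2 = secondary,
#'   3 = tertiary.
#' @export
rasterize_roads <- function(roads, grid) {
  stopifnot_grid(grid)
  out <- matrix(0L, grid$nrows, grid$ncols)
  if (is.null(roads) || nrow(roads) == 0L) return(out)
  code <- match(roads$class, c("primary", "secondary", "tertiary"))
  if (anyNA(code)) {
    stop("unknown road class: ",
         paste(unique(roads$class[is.na(code)]), collapse = ", "))
  }
  for (i in order(code, decreasing = TRUE)) {  # burn low priority first
    cells <- supercover_segment(grid, roads$x0[i], roads$y0[i],
                                roads$x1[i], roads$y1[i])
    out[cells] <- code[i]
  }
  out
}

# Rectangular barrier polygons -> boolean raster (cell-center containment).
rasterize_barriers <- function(barriers, grid) {
  cc <- cell_centers(grid)
  m <- matrix(FALSE, grid$nrows, grid$ncols)
  if (is.null(barriers) || nrow(barriers) == 0L) return(m)
  for (i in seq_len(nrow(barriers))) {
    m <- m | (cc$x >= barriers$xmin[i] & cc$x <= barriers$xmax[i] &
              cc$y >= barriers$ymin[i] & cc$y <= barriers$ymax[i])
  }
  m
}

#' Build a friction (speed) surface for one scenario
#'
#' Combines landcover, rasterized roads and protected-area barriers into a
#' per-cell traversal speed raster. Where a road crosses a cell its class
#' speed strictly overrides the landcover speed. Classes with table speed 0
#' (open water, regularly flooded areas) are impassable. Cells inside
#' barrier polygons are impassable unless a major public road (primary or
#' secondary) transects them; cells outside the study mask are impassable.
#' All speeds are scaled by the scenario multiplier.
#'
#' @param landcover Integer matrix of codes per [landcover_classes].
#' @param road_raster Integer matrix from [rasterize_roads()] (or NULL).
#' @param barriers Data frame of rectangles (`xmin, ymin, xmax, ymax`) or
#'   NULL.
#' @param scenario A [scenario_spec()].
#' @param grid A [grid_spec()].
#' @param mask Optional logical study-mask matrix; cells outside are
#'   impassable.
#' @param barrier_road_classes Road codes that stay passable inside
#'   barriers; default primary and secondary.
#' @return A `friction_surface`: list with `grid`, `speed` (km/h, 0 where
#'   impassable), `passable` (logical), and the `scenario`.
#' @export
build_friction <- function(landcover, road_raster = NULL, barriers = NULL,
                           scenario = scenario_spec("walk"),
                           grid, mask = NULL,
                           barrier_road_classes = c(1L, 2L)) {
  stopifnot_grid(grid)
  stopifnot(nrow(landcover) == grid$nrows, ncol(landcover) == grid$ncols)
  st <- scenario$speed_table
  lc_names <- landcover_classes$name[match(landcover, landcover_classes$code)]
  missing_cls <- setdiff(unique(lc_names[!is.na(landcover)]), names(st))
  if (length(missing_cls))
    stop("landcover class absent from speed_table: ",
         paste(missing_cls, collapse = ", "))
  speed <- matrix(st[lc_names], grid$nrows, grid$ncols)
  if (!is.null(road_raster)) {
    stopifnot(dim(road_raster) == dim(landcover))
    has_road <- road_raster > 0L
    rd_speed <- st[road_class_names[road_raster[has_road]]]
    if (anyNA(rd_speed)) stop("road class absent from speed_table")
    speed[has_road] <- rd_speed
  } else {
    has_road <- matrix(FALSE, grid$nrows, grid$ncols)
  }
  speed <- speed * scenario$multiplier
  speed[is.na(speed)] <- 0
  barrier_mask <- rasterize_barriers(barriers, grid)
  if (!is.null(road_raster)) {
    exempt <- matrix(road_raster %in% barrier_road_classes,
                     grid$nrows, grid$ncols)
  } else exempt <- matrix(FALSE, grid$nrows, grid$ncols)
  speed[barrier_mask & !exempt] <- 0
  if (!is.null(mask)) speed[!mask] <- 0
  passable <- speed > 0
  speed[!passable] <- 0
  structure(list(grid = grid, speed = speed, passable = passable,
                 scenario = scenario),
            class = "friction_surface")
}

#' @export
print.friction_surface <- function(x, ...) {
  cat(sprintf("<friction_surface> %s, multiplier %g: %d/%d passable cells\n",
              x$scenario$mode, x$scenario$multiplier,
              sum(x$passable), length(x$passable)))
  invisible(x)
}
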