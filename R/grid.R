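#' Define a raster grid
#'
#' A `grid_spec` fixes the geometry shared by every raster in an analysis:
#' number of rows and columns, square cell size in meters, and the planar
#' coordinate of the lower-left corner. All layers in a scene share one grid;
#' coordinates are planar meters (projection handling, if any, happens
#' upstream of this package).
#'
#' Rasters are stored as plain R matrices in map orientation: row 1 is the
#' top (northernmost) row, column 1 the westernmost column.
#'
#' @param nrows,ncols Grid dimensions, each at least 2.
#' @param cell_size Cell edge length in meters (> 0).
#' @param origin Numeric length-2, planar (x, y) of the lower-left corner.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(100, 100, cell_size = 1000)
#' @export
grid_spec <- function(nrows, ncols, cell_size, origin = c(0, 0)) {
  nrows <- as.integer(nrows); ncols <- as.integer(ncols)
  if (nrows < 2L || ncols < 2L) stop("grid must be at least 2 x 2")
  if (!is.numeric(cell_size) || cell_size <= 0) stop("cell_size must be > 0")
  structure(list(nrows = nrows, ncols = ncols,
                 cell_size = as.numeric(cell_size),
                 origin = as.numeric(origin)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, %g m, origin (%g, %g)\n",
              x$nrows, x$ncols, x$cell_size, x$origin[1], x$origin[2]))
  invisible(x)
}

stopifnot_grid <- function(grid) {
  if (!inherits(grid, "grid_spec")) stop("expected a grid_spec")
  invisible(grid)
}

check_same_grid <- function(a, b) {
  if (!identical(unclass(a), unclass(b))) stop("rasters do not share one grid")
  invisible(TRUE)
}

#' Cell-center coordinates and point-to-cell lookup
#'
#' `cell_centers()` returns the planar x/y of every cell center.
#' `point_to_cell()` maps planar points to (row, col) indices; points outside
#' the grid extent get NA.
#'
#' @param grid A [grid_spec()].
#' @param x,y Numeric point coordinates.
#' @return `cell_centers()`: a list with matrices `x` and `y` of grid shape.
#'   `point_to_cell()`: a two-column integer matrix (row, col).
#' @export
cell_centers <- function(grid) {
  stopifnot_grid(grid)
  cs <- grid$cell_size
  xs <- grid$origin[1] + (seq_len(grid$ncols) - 0.5) * cs
  ys <- grid$origin[2] + (grid$nrows - seq_len(grid$nrows) + 0.5) * cs
  list(x = matrix(xs, grid$nrows, grid$ncols, byrow = TRUE),
       y = matrix(ys, grid$nrows, grid$ncols))
}

#' @rdname cell_centers
#' @export
point_to_cell <- function(grid, x, y) {
  stopifnot_grid(grid)
  cs <- grid$cell_size
  col <- floor((x - grid$origin[1]) / cs) + 1L
  row <- grid$nrows - floor((y - grid$origin[2]) / cs)
  bad <- col < 1L | col > grid$ncols | row < 1L | row > grid$nrows
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Read and write rasters as ESRI ASCII grids
#'
#' Plain-text raster interchange (.asc) readable by standard GIS software.
#' `+Inf` and `NA` cells are written as the declared NODATA value.
#'
#' @param values Numeric matrix in map orientation.
#' @param grid A [grid_spec()].
#' @param path File path.
#' @param nodata NODATA sentinel written to file.
#' @return `read_ascii_grid()` returns a list with `grid` and `values`.
#' @export
write_ascii_grid <- function(values, grid, path, nodata = -9999) {
  stopifnot_grid(grid)
  stopifnot(nrow(values) == grid$nrows, ncol(values) == grid$ncols)
  v <- values
  v[!is.finite(v)] <- nodata
  hdr <- c(sprintf("ncols %d", grid$ncols),
           sprintf("nrows %d", grid$nrows),
           sprintf("xllcorner %.10g", grid$origin[1]),
           sprintf("yllcorner %.10g", grid$origin[2]),
           sprintf("cellsize %.10g", grid$cell_size),
           sprintf("NODATA_value %g", nodata))
  body <- apply(v, 1L, function(r) paste(format(r, trim = TRUE), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  key <- tolower(vapply(hdr, `[`, "", 1L))
  val <- as.numeric(vapply(hdr, `[`, "", 2L))
  names(val) <- key
  vals <- scan(text = lines[-(1:6)], quiet = TRUE)
  m <- matrix(vals, nrow = val[["nrows"]], ncol = val[["ncols"]], byrow = TRUE)
  m[m == val[["nodata_value"]]] <- NA_real_
  list(grid = grid_spec(val[["nrows"]], val[["ncols"]], val[["cellsize"]],
                        c(val[["xllcorner"]], val[["yllcorner"]])),
       values = m)
}

#' Write point features to GeoJSON
#'
#' @param df Data frame with `x`, `y` columns; remaining columns become
#'   feature properties.
#' @param path Output file.
#' @export
write_points_geojson <- function(df, path) {
  stopifnot(all(c("x", "y") %in% names(df)))
  props <- setdiff(names(df), c("x", "y"))
  feats <- lapply(seq_len(nrow(df)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(df$x[i], df$y[i])),
         properties = as.list(df[i, props, drop = FALSE]))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
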