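#' @useDynLib accesskit, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Impassable sentinel, seconds per cell. Also the initial value of the
# accumulated grid before any scan relaxes it.
SENTINEL <- 99999

#' Rectangular raster grid
#'
#' The substrate for every layer in the toolkit: a numeric matrix with a
#' square cell size in metres and the map coordinates of the lower-left
#' corner. Row 1 of the matrix is the northern edge; map y increases
#' northward. Nodata cells are stored as `NA` and serialised with the
#' `nodata` sentinel (default -9999).
#'
#' Cell centres sit at `origin + (col - 0.5, n_rows - row + 0.5) * cell_size`.
#'
#' @param values numeric matrix, row 1 = north.
#' @param cell_size cell edge length in metres (> 0).
#' @param origin_x,origin_y map coordinates of the lower-left corner.
#' @param nodata numeric sentinel used on disk for `NA` cells.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, cell_size, origin_x = 0, origin_y = 0,
                        nodata = -9999) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         nodata = as.numeric(nodata)),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("raster_grid: %d x %d cells, %g m, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              x$origin_x, x$origin_y))
  rng <- suppressWarnings(range(x$values, na.rm = TRUE))
  cat(sprintf("  values: [%g, %g], %d nodata\n", rng[1], rng[2],
              sum(is.na(x$values))))
  invisible(x)
}

n_rows <- function(g) nrow(g$values)
n_cols <- function(g) ncol(g$values)

is_raster_grid <- function(x) inherits(x, "raster_grid")

#' Check that rasters are co-registered
#'
#' All layers combined in one analysis must share shape, cell size and
#' origin. Called before every multi-layer operation.
#'
#' @param ... `raster_grid` objects.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
check_coregistered <- function(...) {
  gs <- list(...)
  stopifnot(length(gs) >= 1)
  for (g in gs) if (!is_raster_grid(g)) stop("not a raster_grid")
  ref <- gs[[1]]
  for (g in gs[-1]) {
    if (nrow(g$values) != nrow(ref$values) ||
        ncol(g$values) != ncol(ref$values))
      stop("rasters are not co-registered: shapes differ")
    if (g$cell_size != ref$cell_size)
      stop("rasters are not co-registered: cell sizes differ")
    if (g$origin_x != ref$origin_x || g$origin_y != ref$origin_y)
      stop("rasters are not co-registered: origins differ")
  }
  invisible(TRUE)
}

# Same grid geometry, new values.
grid_like <- function(template, values) {
  raster_grid(values, template$cell_size, template$origin_x,
              template$origin_y, template$nodata)
}

#' Map coordinates of cell centres
#' @param grid a `raster_grid`.
#' @param row,col 1-based cell indices (vectors).
#' @return two-column matrix of x, y map coordinates.
#' @export
cell_to_xy <- function(grid, row, col) {
  cbind(x = grid$origin_x + (col - 0.5) * grid$cell_size,
        y = grid$origin_y + (n_rows(grid) - row + 0.5) * grid$cell_size)
}

#' Cell index containing a map coordinate
#'
#' Points are snapped to the nearest cell centre; points on a cell boundary
#' fall into the cell to the east/south of the boundary.
#'
#' @param grid a `raster_grid`.
#' @param x,y map coordinates (vectors).
#' @return two-column integer matrix of row, col; NA outside the extent.
#' @export
xy_to_cell <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1L
  row <- n_rows(grid) - floor((y - grid$origin_y) / grid$cell_size)
  bad <- col < 1L | col > n_cols(grid) | row < 1L | row > n_rows(grid)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

# The 16-neighbour move set of the 5x5 chamfer mask: 4 axial, 4 diagonal,
# 8 knight moves, with exact Euclidean step lengths in cell units.
MOVES <- local({
  dr <- c(-1, 1, 0, 0, -1, -1, 1, 1, -2, -2, -1, -1, 1, 1, 2, 2)
  dc <- c(0, 0, -1, 1, -1, 1, -1, 1, -1, 1, -2, 2, -2, 2, -1, 1)
  data.frame(dr = dr, dc = dc, dist = sqrt(dr^2 + dc^2))
})
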