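# Rasterise classed roads and mosaic vegetation, stream classes and road
# classes into the single twelve-class land-cover grid.

#' Rasterise classed road polylines
#'
#' A cell takes a road class id (201 national, 202 provincial, 203 local)
#' when its centre lies within half a cell size of a road polyline; line
#' tracing is dense enough that rasterised roads form 8-connected chains
#' with no diagonal gaps. Where classes cross, the lower id (faster class)
#' wins. Road parts outside the extent are clipped silently.
#'
#' @param roads a [vector_layer()] of polylines with a `class` attribute.
#' @param grid_spec a [raster_grid()] defining the target geometry.
#' @return a [raster_grid()] of road class ids, 0 where no road.
#' @export
rasterize_roads <- function(roads, grid_spec) {
  stopifnot(inherits(roads, "vector_layer"), is_raster_grid(grid_spec))
  nr <- n_rows(grid_spec); nc <- n_cols(grid_spec)
  cs <- grid_spec$cell_size
  out <- matrix(0L, nr, nc)
  for (f in roads$features) {
    if (f$type != "linestring") next
    cls_name <- f$attributes$class
    if (is.null(cls_name) || !cls_name %in% names(ROAD_CLASSES))
      stop(sprintf("road feature without a valid class attribute (got '%s')",
                   if (is.null(cls_name)) "" else cls_name))
    cls <- ROAD_CLASSES[[cls_name]]
    xy <- f$coords
    for (s in seq_len(nrow(xy) - 1)) {
      cells <- segment_cells(grid_spec, xy[s, ], xy[s + 1, ], cs)
      if (!nrow(cells)) next
      idx <- (cells[, 2] - 1L) * nr + cells[, 1]
      cur <- out[idx]
      take <- cur == 0L | cur > cls
      out[idx[take]] <- cls
    }
  }
  grid_like(grid_spec, out)
}

# Cells whose centre lies within cell_size/2 of the segment a--b, plus the
# supercover of sampled points along it (guarantees 8-connectivity).
segment_cells <- function(grid, a, b, cs) {
  nr <- n_rows(grid); nc <- n_cols(grid)
  len <- sqrt(sum((b - a)^2))
  n_samp <- max(2L, ceiling(len / (cs / 4)) + 1L)
  t <- seq(0, 1, length.out = n_samp)
  px <- a[1] + t * (b[1] - a[1]); py <- a[2] + t * (b[2] - a[2])
  rc <- xy_to_cell(grid, px, py)
  rc <- rc[!is.na(rc[, 1]), , drop = FALSE]
  # widen to the centre-distance criterion: check the 3x3 block around each
  # sampled cell against exact point-segment distance
  if (nrow(rc)) {
    cand <- unique(rbind(
      rc,
      do.call(rbind, lapply(list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                                 c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)),
                            function(d) cbind(rc[, 1] + d[1], rc[, 2] + d[2])))))
    cand <- cand[cand[, 1] >= 1 & cand[, 1] <= nr &
                   cand[, 2] >= 1 & cand[, 2] <= nc, , drop = FALSE]
    ctr <- cell_to_xy(grid, cand[, 1], cand[, 2])
    d <- point_segment_distance(ctr[, 1], ctr[, 2], a, b)
    near <- cand[d <= cs / 2 + 1e-9, , drop = FALSE]
    unique(rbind(rc, near))
  } else rc
}

point_segment_distance <- function(px, py, a, b) {
  vx <- b[1] - a[1]; vy <- b[2] - a[2]
  l2 <- vx^2 + vy^2
  if (l2 == 0) return(sqrt((px - a[1])^2 + (py - a[2])^2))
  t <- pmin(1, pmax(0, ((px - a[1]) * vx + (py - a[2]) * vy) / l2))
  sqrt((px - (a[1] + t * vx))^2 + (py - (a[2] + t * vy))^2)
}

#' Compose the twelve-class land-cover grid
#'
#' Per-cell mosaic with precedence road > stream > vegetation (roads are
#' assumed bridged over watercourses). A cell with vegetation nodata and no
#' road or stream propagates nodata.
#'
#' @param vegetation [raster_grid()] with classes 1-4.
#' @param stream_classes [raster_grid()] with classes 101-105, 0 = none.
#' @param road_classes [raster_grid()] with classes 201-203, 0 = none.
#' @return a [raster_grid()] land-cover grid over the twelve-id vocabulary.
#' @export
compose_landcover <- function(vegetation, stream_classes, road_classes) {
  check_coregistered(vegetation, stream_classes, road_classes)
  veg <- vegetation$values
  if (!all(veg[!is.na(veg)] %in% VEG_CLASSES))
    stop("vegetation raster contains values outside classes 1-4")
  st <- stream_classes$values; rd <- road_classes$values
  st[is.na(st)] <- 0; rd[is.na(rd)] <- 0
  out <- veg
  out[st > 0] <- st[st > 0]
  out[rd > 0] <- rd[rd > 0]
  bad <- !is.na(out) & !(out %in% LANDCOVER_IDS)
  if (any(bad)) stop("composed land cover contains ids outside the schema")
  grid_like(vegetation, out)
}

#' Edit a land-cover grid
#'
#' Applies a list of cell edits in order (later edits win), the raster
#' analogue of drawing roads or cover changes directly onto the grid. All
#' class ids are validated before any cell is touched.
#'
#' @param grid a land-cover [raster_grid()].
#' @param edits list of `list(cells =, class =)` where `cells` is a
#'   two-column matrix of (row, col) and `class` a land-cover id.
#' @return the edited [raster_grid()].
#' @export
edit_landcover <- function(grid, edits) {
  stopifnot(is_raster_grid(grid))
  if (!length(edits)) return(grid)
  for (e in edits) {
    if (is.null(e$class) || length(e$class) != 1 ||
        !e$class %in% LANDCOVER_IDS)
      stop(sprintf("invalid land-cover class id in edit: %s",
                   paste(e$class, collapse = ", ")))
    if (is.null(e$cells)) stop("edit without cells")
  }
  v <- grid$values
  nr <- nrow(v)
  for (e in edits) {
    cells <- matrix(as.integer(e$cells), ncol = 2)
    if (any(cells[, 1] < 1 | cells[, 1] > nr |
            cells[, 2] < 1 | cells[, 2] > ncol(v)))
      stop("edit cells outside the grid extent")
    v[(cells[, 2] - 1L) * nr + cells[, 1]] <- e$class
  }
  grid_like(grid, v)
}
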