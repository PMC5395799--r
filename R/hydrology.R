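# Watercourse derivation from elevation: depression filling, D8 flow
# direction, flow accumulation, Strahler stream ordering and binning into
# the five stream classes of the land-cover schema.

# D8 neighbour order used for steepest-descent tie-breaking: E, SE, S, SW,
# W, NW, N, NE. A fixed order keeps flow directions deterministic across
# platforms.
D8 <- data.frame(
  code = 1:8,
  dr = c(0, 1, 1, 1, 0, -1, -1, -1),
  dc = c(1, 1, 0, -1, -1, -1, 0, 1))
D8$dist <- sqrt(D8$dr^2 + D8$dc^2)

#' Fill depressions in a DEM
#'
#' Priority-flood filling: the grid is flooded inward from its edge in
#' order of increasing elevation, so every depression is raised to its
#' spill elevation. With `eps > 0` (the default) filled flats get a tiny
#' monotone gradient toward the spill point, guaranteeing that D8 flow is
#' defined on every filled cell; with `eps = 0` pits are raised exactly to
#' their spill elevation.
#'
#' @param dem a [raster_grid()] of elevations (m). Nodata cells are treated
#'   as off-analysis; cells bordering them may drain into them.
#' @param eps per-step fill increment in metres (default `1e-6`).
#' @return a [raster_grid()] with `values >= dem$values` everywhere.
#' @export
fill_sinks <- function(dem, eps = 1e-6) {
  stopifnot(is_raster_grid(dem))
  if (all(is.na(dem$values))) stop("fill_sinks: all-nodata DEM")
  grid_like(dem, cpp_fill_sinks(dem$values, eps))
}

#' D8 flow directions
#'
#' Each cell drains to the 8-neighbour with the steepest descent
#' (slope = drop / centre distance). Codes 1..8 follow the order E, SE, S,
#' SW, W, NW, N, NE (ties broken by that order); 0 marks an outlet (no
#' lower neighbour, normally only at the grid edge of a filled DEM).
#'
#' @param dem_filled sink-free [raster_grid()] (see [fill_sinks()]).
#' @return integer matrix of direction codes (NA on nodata).
#' @export
d8_flow <- function(dem_filled) {
  stopifnot(is_raster_grid(dem_filled))
  z <- dem_filled$values
  nr <- nrow(z); nc <- ncol(z)
  best_slope <- matrix(0, nr, nc)
  dir <- matrix(0L, nr, nc)
  for (k in seq_len(8)) {
    zn <- shift_mat(z, D8$dr[k], D8$dc[k])
    slope <- (z - zn) / D8$dist[k]
    upd <- !is.na(slope) & slope > best_slope
    best_slope[upd] <- slope[upd]
    dir[upd] <- D8$code[k]
  }
  dir[is.na(z)] <- NA_integer_
  dir
}

# Shift a matrix by (dr, dc), padding with NA: result[r,c] = m[r+dr, c+dc].
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs - dr, cs - dc] <- m[rs, cs]
  out
}

# Flat index of the receiver cell for each cell (NA for outlets/nodata).
receiver_index <- function(flowdir) {
  nr <- nrow(flowdir); nc <- ncol(flowdir)
  idx <- which(!is.na(flowdir) & flowdir > 0L)
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  k <- flowdir[idx]
  rr <- r + D8$dr[k]; cc <- c + D8$dc[k]
  ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
  recv <- rep(NA_integer_, nr * nc)
  recv[idx[ok]] <- (cc[ok] - 1L) * nr + rr[ok]
  recv
}

# Topological order of the flow graph (upstream first). Errors if the
# graph has a cycle, which a filled DEM cannot produce.
flow_topo_order <- function(flowdir) {
  recv <- receiver_index(flowdir)
  n <- length(recv)
  cells <- which(!is.na(flowdir))
  indeg <- tabulate(recv[!is.na(recv)], nbins = n)
  queue <- integer(length(cells))
  seeds <- cells[indeg[cells] == 0L]
  queue[seq_along(seeds)] <- seeds
  tail <- length(seeds)
  head <- 1L
  while (head <= tail) {
    cur <- queue[head]; head <- head + 1L
    nxt <- recv[cur]
    if (!is.na(nxt)) {
      indeg[nxt] <- indeg[nxt] - 1L
      if (indeg[nxt] == 0L) { tail <- tail + 1L; queue[tail] <- nxt }
    }
  }
  if (tail != length(cells)) stop("flow graph contains a cycle")
  queue
}

#' Flow accumulation
#'
#' Counts the number of cells draining through each cell, including the
#' cell itself; the accumulation at an outlet equals its catchment size.
#'
#' @param flowdir D8 direction matrix from [d8_flow()].
#' @return numeric matrix of upstream cell counts (NA on nodata).
#' @export
flow_accumulation <- function(flowdir) {
  recv <- receiver_index(flowdir)
  acc <- rep(NA_real_, length(recv))
  cells <- which(!is.na(flowdir))
  acc[cells] <- 1
  for (cur in flow_topo_order(flowdir)) {
    nxt <- recv[cur]
    if (!is.na(nxt)) acc[nxt] <- acc[nxt] + acc[cur]
  }
  matrix(acc, nrow(flowdir), ncol(flowdir))
}

#' Strahler stream ordering
#'
#' Cells whose flow accumulation meets the initiation threshold are stream
#' cells. Headwater stream cells take order 1; where two inflowing streams
#' share the maximum order n the downstream cell takes n + 1; a lower-order
#' tributary leaves the order unchanged.
#'
#' @param flowdir D8 direction matrix.
#' @param accumulation matrix from [flow_accumulation()].
#' @param stream_threshold_cells minimum accumulation (in cells) for a cell
#'   to carry a stream (default 0.5\% of the grid's cells).
#' @return integer matrix: Strahler order on stream cells, 0 elsewhere.
#' @export
strahler <- function(flowdir, accumulation,
                     stream_threshold_cells = max(1, round(0.005 * length(flowdir)))) {
  if (stream_threshold_cells < 1) stop("stream threshold must be >= 1 cell")
  recv <- receiver_index(flowdir)
  stream <- !is.na(accumulation) & accumulation >= stream_threshold_cells
  ord <- rep(0L, length(recv))
  # inflow bookkeeping along topological order: track, per stream cell, the
  # maximum inflowing stream order and how many inflows attain it
  max_in <- rep(0L, length(recv))
  n_at_max <- rep(0L, length(recv))
  for (cur in flow_topo_order(flowdir)) {
    if (!stream[cur]) next
    o <- if (max_in[cur] == 0L) 1L
         else if (n_at_max[cur] >= 2L) max_in[cur] + 1L
         else max_in[cur]
    ord[cur] <- o
    nxt <- recv[cur]
    if (!is.na(nxt) && stream[nxt]) {
      if (o > max_in[nxt]) { max_in[nxt] <- o; n_at_max[nxt] <- 1L }
      else if (o == max_in[nxt]) n_at_max[nxt] <- n_at_max[nxt] + 1L
    }
  }
  matrix(ord, nrow(flowdir), ncol(flowdir))
}

#' Bin Strahler orders into the five stream land-cover classes
#'
#' Orders 1-4 map to classes 101-104; orders 5 and above are capped into
#' class 105 (the largest watercourses, unlikely to be passable at any time
#' of year). Non-stream cells map to 0.
#'
#' @param streams integer matrix from [strahler()].
#' @param template [raster_grid()] supplying the grid geometry.
#' @return a [raster_grid()] of stream class ids (0 = no stream).
#' @export
streams_to_classes <- function(streams, template) {
  cls <- streams
  cls[streams >= 1L & streams <= 4L] <- 100L + streams[streams >= 1L & streams <= 4L]
  cls[streams >= 5L] <- 105L
  grid_like(template, cls)
}

#' Derive stream classes straight from a DEM
#'
#' Convenience wrapper: fill sinks, D8 flow, accumulation, Strahler order,
#' class binning.
#'
#' @inheritParams fill_sinks
#' @inheritParams strahler
#' @return a [raster_grid()] of stream class ids (0 = no stream).
#' @export
derive_streams <- function(dem, stream_threshold_cells =
                             max(1, round(0.005 * length(dem$values)))) {
  filled <- fill_sinks(dem)
  fd <- d8_flow(filled)
  acc <- flow_accumulation(fd)
  streams_to_classes(strahler(fd, acc, stream_threshold_cells), dem)
}
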