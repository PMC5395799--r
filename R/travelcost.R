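# Scenario-parameterised friction surfaces, accumulated travel time to
# destinations (chamfer transform and exact Dijkstra), travel-zone
# classification.

WALK_FACTORS <- c(walking = 1, assisted = 0.5, stretcher = 0.2)

#' Travel scenario specification
#'
#' Bundles the modifiers that turn one land-cover grid into one friction
#' surface: patient mobility (`walking`, `assisted` halves walking speed,
#' `stretcher` cuts it to a fifth), time of day (night slows all travel by
#' 20\%), weather (`rainy` makes the three highest stream classes
#' impassable, `flooding` all five), optional per-road-class speed
#' overrides (km/h), drawn land-cover edits, drawn barriers (minutes per
#' cell, 1-600), and a service-availability factor.
#'
#' @param walking_mode one of `walking`, `assisted`, `stretcher`.
#' @param time_of_day `day` or `night`.
#' @param weather `dry`, `rainy` or `flooding`.
#' @param road_speed_overrides named numeric vector, names are road class
#'   ids (201-203), values km/h; `NULL` for none.
#' @param barriers list of `list(cells =, minutes =)`; each barrier sets
#'   its cells to `minutes * 60` seconds of traversal time, minutes in
#'   `[1, 600]`.
#' @param drawn_roads land-cover edits as in [edit_landcover()].
#' @param destinations optional [vector_layer()] of points.
#' @param service `doctor_in` or `doctor_away` (see
#'   [service_availability()]).
#' @param walking_slows_roads apply the walking-mode factor to road classes
#'   too (default `FALSE`: road travel is assumed vehicular).
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(walking_mode = "walking", time_of_day = "day",
                          weather = "dry", road_speed_overrides = NULL,
                          barriers = list(), drawn_roads = list(),
                          destinations = NULL, service = "doctor_in",
                          walking_slows_roads = FALSE) {
  walking_mode <- match.arg(walking_mode, names(WALK_FACTORS))
  time_of_day <- match.arg(time_of_day, c("day", "night"))
  weather <- match.arg(weather, c("dry", "rainy", "flooding"))
  service <- match.arg(service, c("doctor_in", "doctor_away"))
  if (!is.null(road_speed_overrides)) {
    ids <- suppressWarnings(as.integer(names(road_speed_overrides)))
    if (anyNA(ids) || !all(ids %in% 201:203))
      stop("road_speed_overrides must be named by road class ids 201-203")
    if (any(road_speed_overrides < 0)) stop("override speeds must be >= 0")
  }
  for (b in barriers) {
    if (is.null(b$minutes) || b$minutes < 1 || b$minutes > 600)
      stop("barrier minutes must lie in [1, 600]")
    if (is.null(b$cells)) stop("barrier without cells")
  }
  structure(list(walking_mode = walking_mode, time_of_day = time_of_day,
                 weather = weather,
                 road_speed_overrides = road_speed_overrides,
                 barriers = barriers, drawn_roads = drawn_roads,
                 destinations = destinations, service = service,
                 walking_slows_roads = walking_slows_roads),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("scenario: %s / %s / %s / %s\n", x$walking_mode,
              x$time_of_day, x$weather, x$service))
  invisible(x)
}

#' Read a scenario from a YAML config
#'
#' Field-for-field mirror of [scenario_spec()]; unlisted fields take their
#' defaults.
#'
#' @param path YAML file.
#' @return a `scenario_spec`.
#' @export
read_scenario_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- names(formals(scenario_spec))
  unknown <- setdiff(names(y), allowed)
  if (length(unknown))
    stop(sprintf("unknown scenario field(s): %s",
                 paste(unknown, collapse = ", ")))
  if (!is.null(y$road_speed_overrides))
    y$road_speed_overrides <- unlist(y$road_speed_overrides)
  do.call(scenario_spec, y)
}

#' Snap destination points to grid cells
#'
#' Each point snaps to the nearest cell centre; points snapping to the
#' same cell collapse to one (with a message). The set must be non-empty
#' and inside the extent.
#'
#' @param points a [vector_layer()] of point features.
#' @param grid a [raster_grid()].
#' @return integer matrix with columns `row`, `col`, one row per distinct
#'   destination cell, of class `destination_set`.
#' @export
snap_destinations <- function(points, grid) {
  stopifnot(inherits(points, "vector_layer"))
  pts <- Filter(function(f) f$type == "point", points$features)
  if (!length(pts)) stop("destination set is empty")
  xy <- do.call(rbind, lapply(pts, function(f) f$coords[1, ]))
  rc <- xy_to_cell(grid, xy[, 1], xy[, 2])
  if (anyNA(rc)) stop("destination point outside the grid extent")
  dup <- duplicated(rc)
  if (any(dup)) {
    message(sprintf("%d destination(s) collapsed onto shared cells", sum(dup)))
    rc <- rc[!dup, , drop = FALSE]
  }
  structure(rc, class = c("destination_set", class(rc)))
}

#' Build the per-cell friction (cost) surface for a scenario
#'
#' Converts land-cover classes to traversal seconds via the speed lookup
#' (`seconds = cell_size / (kmh * 1000/3600)`; 0 km/h is the 99,999 s
#' impassable sentinel), then applies the scenario modifiers in a fixed
#' order: drawn land-cover edits, road-speed overrides, walking-mode
#' factor on non-road classes, weather closures, the night factor
#' (speed x 0.8, i.e. seconds x 1.25), and finally drawn barriers, which
#' always win.
#'
#' @param lc land-cover [raster_grid()].
#' @param lookup a `speed_lookup` from [read_lookup_csv()].
#' @param scenario a [scenario_spec()].
#' @return a [raster_grid()] of seconds per cell, of class `cost_grid`.
#' @export
build_cost_grid <- function(lc, lookup, scenario = scenario_spec()) {
  stopifnot(is_raster_grid(lc), inherits(lookup, "speed_lookup"),
            inherits(scenario, "scenario_spec"))
  # (1) drawn roads / cover edits
  if (length(scenario$drawn_roads))
    lc <- edit_landcover(lc, scenario$drawn_roads)
  present <- sort(unique(lc$values[!is.na(lc$values)]))
  missing <- setdiff(present, lookup$id)
  if (length(missing))
    stop(sprintf("no speed lookup entry for class id(s): %s",
                 paste(missing, collapse = ", ")))
  kmh <- stats::setNames(lookup$kmh, lookup$id)
  # (2) road speed overrides
  if (!is.null(scenario$road_speed_overrides)) {
    ov <- scenario$road_speed_overrides
    kmh[names(ov)] <- ov
  }
  # (3) walking-mode factor off-road (road travel is vehicular)
  wf <- WALK_FACTORS[[scenario$walking_mode]]
  ids <- as.integer(names(kmh))
  walkable <- if (scenario$walking_slows_roads) rep(TRUE, length(ids))
              else ids < 200L
  kmh[walkable] <- kmh[walkable] * wf
  # (4) weather closures
  closed <- switch(scenario$weather, dry = integer(0),
                   rainy = c(103L, 104L, 105L), flooding = 101:105)
  kmh[as.character(closed)] <- 0
  # seconds per cell
  secs <- ifelse(kmh > 0, lc$cell_size / (kmh * 1000 / 3600), SENTINEL)
  # (5) night: all travel slowed by twenty percent
  if (scenario$time_of_day == "night")
    secs <- ifelse(secs < SENTINEL, secs * 1.25, secs)
  secs <- pmin(secs, SENTINEL)
  cost <- matrix(secs[as.character(lc$values)], n_rows(lc), n_cols(lc))
  # (6) barriers always win
  nr <- n_rows(lc)
  for (b in scenario$barriers) {
    cells <- matrix(as.integer(b$cells), ncol = 2)
    cost[(cells[, 2] - 1L) * nr + cells[, 1]] <- b$minutes * 60
  }
  out <- grid_like(lc, cost)
  class(out) <- c("cost_grid", class(out))
  out
}

check_destinations <- function(cost, dest) {
  if (is.null(dest) || nrow(dest) == 0) stop("destination set is empty")
  v <- cost$values[(dest[, 2] - 1L) * n_rows(cost) + dest[, 1]]
  if (anyNA(v) || any(v >= SENTINEL))
    stop("destination lies on an impassable (sentinel) cell")
  invisible(TRUE)
}

#' Accumulated travel time by chamfer distance transform
#'
#' The accumulated grid is initialised to the 99,999 s sentinel with
#' destination cells at 0, then relaxed by four sequential scans (row-major
#' forward and backward, column-major forward and backward) of a 5 x 5
#' mask whose sixteen moves carry exact Euclidean step lengths 1, sqrt(2)
#' and sqrt(5) cell units; each move costs its length times the mean of the
#' two cells' traversal seconds. Cells at the sentinel are hard barriers.
#'
#' @param cost a `cost_grid` from [build_cost_grid()].
#' @param dest a `destination_set` from [snap_destinations()].
#' @param scan_pairs number of scan quartets (default 1 = the standard four
#'   scans).
#' @param converge repeat scan quartets until no cell changes (overrides
#'   `scan_pairs`).
#' @return a [raster_grid()] of accumulated seconds, class
#'   `travel_time_grid`; unreachable cells hold the sentinel.
#' @export
chamfer_travel_time <- function(cost, dest, scan_pairs = 1,
                                converge = FALSE) {
  stopifnot(is_raster_grid(cost))
  check_destinations(cost, dest)
  acc <- matrix(SENTINEL, n_rows(cost), n_cols(cost))
  acc[(dest[, 2] - 1L) * n_rows(cost) + dest[, 1]] <- 0
  res <- cpp_chamfer(cost$values, acc, SENTINEL, as.integer(scan_pairs),
                     isTRUE(converge))
  out <- grid_like(cost, res$acc)
  attr(out, "quartets") <- res$quartets
  class(out) <- c("travel_time_grid", class(out))
  out
}

# Cells flanking the midpoint of a knight move (dr, dc).
knight_mids <- function(dr, dc) {
  if (abs(dr) == 2) rbind(c(dr / 2, 0), c(dr / 2, dc))
  else rbind(c(0, dc / 2), c(dr, dc / 2))
}

# Build the 16-neighbour move graph over passable cells once; returns the
# igraph plus the flat indices of passable cells.
move_graph <- function(cost) {
  v <- cost$values
  nr <- nrow(v); nc <- ncol(v)
  passable <- !is.na(v) & v < SENTINEL
  id <- matrix(NA_integer_, nr, nc)
  id[passable] <- seq_len(sum(passable))
  edges <- vector("list", 8)
  w <- vector("list", 8)
  # undirected graph: half of the 16 moves is enough
  half <- MOVES[MOVES$dr > 0 | (MOVES$dr == 0 & MOVES$dc > 0), ]
  for (k in seq_len(nrow(half))) {
    dr <- half$dr[k]; dc <- half$dc[k]; d <- half$dist[k]
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    a <- id[r1, c1, drop = FALSE]
    b <- id[r1 + dr, c1 + dc, drop = FALSE]
    va <- v[r1, c1, drop = FALSE]
    vb <- v[r1 + dr, c1 + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (d > 2) {
      # knight move: both cells flanking the midpoint must be passable,
      # so one-cell-thick barriers cannot be jumped
      m <- knight_mids(dr, dc)
      ok <- ok & passable[cbind(as.vector(row(a)) + r1[1] - 1 + m[1, 1],
                                as.vector(col(a)) + c1[1] - 1 + m[1, 2])] &
        passable[cbind(as.vector(row(a)) + r1[1] - 1 + m[2, 1],
                       as.vector(col(a)) + c1[1] - 1 + m[2, 2])]
    }
    edges[[k]] <- rbind(a[ok], b[ok])
    w[[k]] <- d * (va[ok] + vb[ok]) / 2
  }
  g <- igraph::make_empty_graph(n = sum(passable), directed = FALSE)
  g <- igraph::add_edges(g, as.vector(do.call(cbind, edges)))
  igraph::E(g)$weight <- unlist(w)
  list(graph = g, id = id)
}

#' Accumulated travel time by exact multi-source Dijkstra
#'
#' Exact shortest accumulated time on the same 16-neighbour move graph and
#' move-cost definition as the chamfer engine; serves as the reference
#' (isotropic cost-distance) engine.
#'
#' @inheritParams chamfer_travel_time
#' @return a [raster_grid()] of accumulated seconds, class
#'   `travel_time_grid`; unreachable cells hold the sentinel.
#' @export
dijkstra_travel_time <- function(cost, dest) {
  stopifnot(is_raster_grid(cost))
  check_destinations(cost, dest)
  mg <- move_graph(cost)
  src <- mg$id[(dest[, 2] - 1L) * n_rows(cost) + dest[, 1]]
  d <- igraph::distances(mg$graph, v = src, algorithm = "dijkstra")
  dmin <- if (nrow(d) > 1) apply(d, 2, min) else as.vector(d)
  acc <- matrix(SENTINEL, n_rows(cost), n_cols(cost))
  acc[!is.na(mg$id)] <- pmin(dmin[mg$id[!is.na(mg$id)]], SENTINEL)
  out <- grid_like(cost, acc)
  class(out) <- c("travel_time_grid", class(out))
  out
}

#' Classify accumulated travel time into zones
#'
#' Seconds are converted to minutes and binned by the zone table's
#' half-open `[min, max)` intervals. Sentinel (unreachable) cells fall in
#' the top class; nodata propagates.
#'
#' @param tt a `travel_time_grid`.
#' @param zones a `zone_table` from [read_zone_csv()].
#' @return a [raster_grid()] of zone classes, class `zone_grid`.
#' @export
classify_zones <- function(tt, zones) {
  stopifnot(is_raster_grid(tt), inherits(zones, "zone_table"))
  minutes <- tt$values / 60
  k <- findInterval(minutes, zones$min_minutes)
  k[k > nrow(zones)] <- nrow(zones)
  k[!is.na(minutes) & minutes >= zones$max_minutes[nrow(zones)]] <- nrow(zones)
  k[!is.na(tt$values) & tt$values >= SENTINEL] <- nrow(zones)
  z <- matrix(zones$class[k], n_rows(tt), n_cols(tt))
  z[is.na(tt$values)] <- NA
  out <- grid_like(tt, z)
  class(out) <- c("zone_grid", class(out))
  out
}
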