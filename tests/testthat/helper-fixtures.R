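# Fixtures are generated in code, once per test run, and cached.

.fixture_cache <- new.env(parent = emptyenv())

# Full synthetic pipeline products at test scale (100 x 100, 50 m cells).
pipeline_fixture <- function(seed = 7, n = 100) {
  key <- paste0("pipe_", seed, "_", n)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  fx <- generate_landscape(seed, n, n)
  streams <- derive_streams(fx$dem)
  roads <- rasterize_roads(fx$roads, fx$dem)
  lc <- compose_landcover(fx$vegetation, streams, roads)
  out <- list(
    fx = fx, streams = streams, roads = roads, lc = lc,
    lookup = read_lookup_csv(accesskit_table("speed_table.csv")),
    zones = read_zone_csv(accesskit_table("zone_table.csv")),
    dest = snap_destinations(fx$destinations, lc))
  .fixture_cache[[key]] <- out
  out
}

# Uniform friction surface: every cell costs `secs` to cross.
uniform_cost <- function(n = 41, secs = 90, cell = 50) {
  g <- raster_grid(matrix(secs, n, n), cell)
  class(g) <- c("cost_grid", class(g))
  g
}

# Smooth correlated friction surface in [lo, hi] seconds.
smooth_cost <- function(seed, n = 100, lo = 60, hi = 200, cell = 50) {
  set.seed(seed)
  z <- matrix(rnorm(15 * 15), 15, 15)
  zz <- accesskit:::bilinear_upsample(z, n, n)
  vals <- lo + (hi - lo) * (zz - min(zz)) / diff(range(zz))
  g <- raster_grid(vals, cell)
  class(g) <- c("cost_grid", class(g))
  g
}

dest_at <- function(row, col) {
  m <- cbind(row = as.integer(row), col = as.integer(col))
  structure(m, class = c("destination_set", class(m)))
}

# A small land-cover mosaic containing every feature type of the schema:
# all four vegetation classes, all five stream classes, all three roads.
all_classes_landcover <- function() {
  n <- 20
  veg <- raster_grid(matrix(rep(1:4, each = n * n / 4), n, n), 50)
  st <- matrix(0, n, n)
  st[10, 3:18] <- rep(101:105, length.out = 16)   # a stream run
  streams <- raster_grid(st, 50)
  rd <- matrix(0, n, n)
  rd[15, ] <- 201; rd[, 15] <- ifelse(rd[, 15] == 0, 202, rd[, 15])
  rd[3, 1:8] <- 203
  roads <- raster_grid(rd, 50)
  compose_landcover(veg, streams, roads)
}

# Straight-road fixture for the agent simulation: all-grass plain, one
# national road along the middle row, destination on the road near the
# east edge.
road_plain_fixture <- function(n = 60) {
  key <- paste0("plain_", n)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  lcv <- matrix(2, n, n)
  lcv[n %/% 2, ] <- 201
  lc <- raster_grid(lcv, 50)
  lookup <- read_lookup_csv(accesskit_table("speed_table.csv"))
  cost <- build_cost_grid(lc, lookup)
  dest <- dest_at(n %/% 2, n - 3)
  tt <- dijkstra_travel_time(cost, dest)
  out <- list(lc = lc, cost = cost, dest = dest, tt = tt, lookup = lookup)
  .fixture_cache[[key]] <- out
  out
}
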