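lookup <- read_lookup_csv(accesskit_table("speed_table.csv"))
zones <- read_zone_csv(accesskit_table("zone_table.csv"))

# one cell of each class at 50 m
lc12 <- local({
  g <- raster_grid(matrix(c(1:4, 101:105, 201:203, 2, 2, 2, 2), 4, 4), 50)
  g
})

cost_of <- function(class_id, scenario = scenario_spec()) {
  g <- raster_grid(matrix(class_id, 1, 1), 50)
  build_cost_grid(g, lookup, scenario)$values[1, 1]
}

test_that("per-cell traversal seconds reproduce the reclassification table", {
  expect_equal(cost_of(1), 180)      # Forest, 1 km/h
  expect_equal(cost_of(2), 90)       # Grass, 2 km/h
  expect_equal(cost_of(3), 60)       # Bare, 3 km/h
  expect_equal(cost_of(4), 240)      # Scrub, 0.75 km/h
  for (id in 101:104) expect_equal(cost_of(id), 90)  # wadeable streams
  expect_equal(cost_of(105), 99999)  # largest watercourse: impassable
  expect_equal(cost_of(201), 3.6)    # 50 km/h
  expect_equal(cost_of(202), 7.2)    # 25 km/h
  expect_equal(cost_of(203), 18)     # 10 km/h
})

test_that("scenario modifiers compose in the fixed order", {
  # walking modes scale off-road speeds only
  expect_equal(cost_of(1, scenario_spec(walking_mode = "assisted")), 360)
  expect_equal(cost_of(1, scenario_spec(walking_mode = "stretcher")), 900)
  expect_equal(cost_of(201, scenario_spec(walking_mode = "stretcher")), 3.6)
  expect_equal(cost_of(201, scenario_spec(walking_mode = "stretcher",
                                          walking_slows_roads = TRUE)), 18)
  # night multiplies every passable cell's seconds by 1.25
  expect_equal(cost_of(2, scenario_spec(time_of_day = "night")), 112.5)
  expect_equal(cost_of(105, scenario_spec(time_of_day = "night")), 99999)
  # weather closures
  expect_equal(cost_of(103, scenario_spec(weather = "rainy")), 99999)
  expect_equal(cost_of(102, scenario_spec(weather = "rainy")), 90)
  expect_equal(cost_of(101, scenario_spec(weather = "flooding")), 99999)
  # road speed overrides
  expect_equal(cost_of(202, scenario_spec(road_speed_overrides = c("202" = 50))),
               3.6)
  # barriers override everything else, in minutes * 60 seconds
  sc <- scenario_spec(time_of_day = "night",
                      barriers = list(list(cells = rbind(c(1, 1)),
                                           minutes = 30)))
  expect_equal(cost_of(2, sc), 1800)
  expect_error(scenario_spec(barriers = list(list(cells = rbind(c(1, 1)),
                                                  minutes = 700))),
               "\\[1, 600\\]")
  # missing lookup entry names the class id
  tiny <- lookup[lookup$id != 4, ]
  class(tiny) <- class(lookup)
  g4 <- raster_grid(matrix(4, 1, 1), 50)
  expect_error(build_cost_grid(g4, tiny, scenario_spec()), "4")
})

test_that("drawn road edits change the class before the lookup", {
  g <- raster_grid(matrix(1, 3, 3), 50)
  sc <- scenario_spec(drawn_roads = list(list(cells = rbind(c(2, 1), c(2, 2), c(2, 3)),
                                              class = 203)))
  cg <- build_cost_grid(g, lookup, sc)
  expect_equal(cg$values[2, ], rep(18, 3))
  expect_equal(cg$values[1, ], rep(180, 3))
})

test_that("destination snapping collapses duplicates and validates the extent", {
  g <- raster_grid(matrix(2, 10, 10), 50)
  pts <- vector_layer(list(
    accesskit:::feature("point", c(125, 125)),
    accesskit:::feature("point", c(130, 140)),   # same cell
    accesskit:::feature("point", c(475, 475))))
  expect_message(d <- snap_destinations(pts, g), "collapsed")
  expect_equal(nrow(d), 2)
  out <- vector_layer(list(accesskit:::feature("point", c(-10, 125))))
  expect_error(snap_destinations(out, g), "outside")
  expect_error(snap_destinations(vector_layer(), g), "empty")
})

test_that("both engines satisfy the destination and barrier contracts", {
  cg <- uniform_cost(15, 90)
  d <- dest_at(8, 8)
  for (engine in list(chamfer_travel_time, dijkstra_travel_time)) {
    tt <- engine(cg, d)
    expect_equal(tt$values[8, 8], 0)
    expect_equal(tt$values[8, 9], 90)        # axial neighbour: 1 x (90+90)/2
    expect_equal(tt$values[7, 7], 90 * sqrt(2))
    expect_equal(sum(tt$values == 0), 1)
  }
  # empty and impassable destinations are rejected
  expect_error(chamfer_travel_time(cg, dest_at(integer(0), integer(0))), "empty")
  blocked <- cg; blocked$values[2, 2] <- 99999
  expect_error(dijkstra_travel_time(blocked, dest_at(2, 2)), "impassable")
})

test_that("uniform grid closed form: straight-line axial time is k * cell seconds", {
  cg <- uniform_cost(21, 60)
  tt <- dijkstra_travel_time(cg, dest_at(11, 3))
  expect_equal(tt$values[11, 3 + (0:17)], 60 * (0:17))
})

test_that("chamfer matches Dijkstra on tiny grids and Dijkstra matches Bellman-Ford", {
  for (s in 1:5) {
    cg <- smooth_cost(s, n = 8, lo = 30, hi = 300)
    d <- dest_at(sample(2:7, 1), sample(2:7, 1))
    bf <- bellman_ford_tt(cg$values, d)
    dj <- dijkstra_travel_time(cg, d)
    expect_equal(dj$values, bf, tolerance = 1e-10)
    ch <- chamfer_travel_time(cg, d, converge = TRUE)
    expect_equal(ch$values, bf, tolerance = 1e-10)
  }
})

test_that("seeded 20x20 cost grids keep the chamfer within 5% of the exact engine", {
  for (s in 1:5) {
    cg <- smooth_cost(s, n = 20)
    d <- dest_at(10, 10)
    ch <- chamfer_travel_time(cg, d)
    dj <- dijkstra_travel_time(cg, d)
    fin <- dj$values > 0
    expect_lt(max(abs(ch$values[fin] - dj$values[fin]) / dj$values[fin]), 0.05)
  }
})

test_that("a closed sentinel ring leaves the enclosed cells unreachable in both engines", {
  cg <- uniform_cost(21, 90)
  ring <- cg$values
  ring[6, 6:16] <- 99999; ring[16, 6:16] <- 99999
  ring[6:16, 6] <- 99999; ring[6:16, 16] <- 99999
  cg$values <- ring
  d <- dest_at(2, 2)   # destination outside the ring
  for (engine in list(chamfer_travel_time, dijkstra_travel_time)) {
    tt <- engine(cg, d)
    inside <- tt$values[8:14, 8:14]
    expect_true(all(inside == 99999))
    expect_lt(tt$values[2, 3], 99999)
  }
})

test_that("monotonicity: raising one cell's cost never decreases any travel time", {
  cg <- smooth_cost(3, n = 25)
  d <- dest_at(13, 13)
  base_c <- chamfer_travel_time(cg, d)$values
  base_d <- dijkstra_travel_time(cg, d)$values
  worse <- cg
  worse$values[5, 18] <- worse$values[5, 18] * 10
  expect_true(all(chamfer_travel_time(worse, d)$values >= base_c - 1e-9))
  expect_true(all(dijkstra_travel_time(worse, d)$values >= base_d - 1e-9))
})

test_that("scaling law: costs x f scale travel times by exactly f", {
  cg <- smooth_cost(4, n = 25)
  d <- dest_at(5, 20)
  f <- 1.25
  scaled <- cg; scaled$values <- cg$values * f
  dj1 <- dijkstra_travel_time(cg, d)$values
  dj2 <- dijkstra_travel_time(scaled, d)$values
  fin <- dj1 < 99999
  expect_equal(dj2[fin], f * dj1[fin], tolerance = 1e-12)
  ch1 <- chamfer_travel_time(cg, d)$values
  ch2 <- chamfer_travel_time(scaled, d)$values
  expect_equal(ch2[fin], f * ch1[fin], tolerance = 1e-9)
})

test_that("adding a destination never increases any cell's travel time", {
  cg <- smooth_cost(6, n = 30)
  one <- dijkstra_travel_time(cg, dest_at(5, 5))$values
  two <- dijkstra_travel_time(cg, dest_at(c(5, 25), c(5, 25)))$values
  expect_true(all(two <= one + 1e-9))
})

test_that("every finite non-destination cell has a strictly smaller 16-neighbour", {
  p <- pipeline_fixture()
  cost <- build_cost_grid(p$lc, p$lookup)
  for (tt in list(dijkstra_travel_time(cost, p$dest),
                  chamfer_travel_time(cost, p$dest))) {
    v <- tt$values
    ok <- TRUE
    for (idx in which(v > 0 & v < 99999)) {
      r <- (idx - 1) %% nrow(v) + 1; c <- (idx - 1) %/% nrow(v) + 1
      stp <- accesskit:::descend_step(v, c(r, c))
      if (is.null(stp)) { ok <- FALSE; break }
    }
    expect_true(ok)
  }
})

test_that("zone classification follows the half-open minute intervals", {
  mk_tt <- function(mins) {
    g <- raster_grid(matrix(mins * 60, 1, length(mins)), 50)
    class(g) <- c("travel_time_grid", class(g))
    g
  }
  z <- classify_zones(mk_tt(c(0, 14.9, 15, 29.9, 30, 100, 119.9, 121, 5000)),
                      zones)
  expect_equal(as.vector(z$values), c(1, 1, 2, 2, 3, 5, 5, 6, 6))
  # sentinel (unreachable) cells land in the top class
  g <- mk_tt(1); g$values[1, 1] <- 99999
  expect_equal(classify_zones(g, zones)$values[1, 1], 6)
})
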