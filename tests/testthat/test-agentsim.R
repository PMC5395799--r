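test_that("simulation initialisation validates the patient cell and car setup", {
  f <- road_plain_fixture()
  st <- init_simulation(f$tt, f$lc, f$cost, c(5, 5), seed = 1)
  expect_s3_class(st, "simulation_state")
  expect_length(st$cars, 0)
  # unreachable patient cell rejected
  blocked <- f$tt; blocked$values[2, 2] <- 99999
  expect_error(init_simulation(blocked, f$lc, f$cost, c(2, 2)), "unreachable")
  # cars disabled or zero traffic: no car ever appears
  st0 <- init_simulation(f$tt, f$lc, f$cost, c(5, 5), traffic_intensity = 0,
                         use_cars = TRUE, seed = 1)
  r0 <- run_simulation(st0)
  expect_length(r0$state$cars, 0)
  expect_null(r0$pickup)
})

test_that("degenerate starts terminate immediately or in one step", {
  f <- road_plain_fixture()
  at_dest <- init_simulation(f$tt, f$lc, f$cost, f$dest[1, ], seed = 1)
  res <- run_simulation(at_dest)
  expect_true(res$arrived)
  expect_equal(res$elapsed_min, 0)
  expect_equal(res$distance_km, 0)

  # one axial cell away on a uniform 90 s surface: one step, 90 s, one cell
  cg <- uniform_cost(9, 90)
  d <- dest_at(5, 5)
  tt <- dijkstra_travel_time(cg, d)
  lc <- raster_grid(matrix(2, 9, 9), 50)
  st <- init_simulation(tt, lc, cg, c(5, 4), seed = 1)
  res <- run_simulation(st)
  expect_true(res$arrived)
  expect_equal(res$n_steps, 1)
  expect_equal(res$elapsed_min, 1.5)          # 90 s
  expect_equal(res$distance_km, 0.05)         # one 50 m cell
})

test_that("same seed reproduces identical trajectories with cars", {
  f <- road_plain_fixture()
  run <- function(seed) run_simulation(init_simulation(
    f$tt, f$lc, f$cost, c(5, 30), traffic_intensity = 6, use_cars = TRUE,
    seed = seed))
  a <- run(11); b <- run(11)
  expect_identical(a$trajectory, b$trajectory)
  expect_equal(a$elapsed_min, b$elapsed_min)
  expect_identical(length(a$state$cars), length(b$state$cars))
})

test_that("walking-only arrival time tracks the travel-time surface within 10%", {
  p <- pipeline_fixture()
  cost <- build_cost_grid(p$lc, p$lookup)
  tt_exact <- dijkstra_travel_time(cost, p$dest)
  tt_ch <- chamfer_travel_time(cost, p$dest, converge = TRUE)
  fin <- which(tt_exact$values > 0 & tt_exact$values < 99999, arr.ind = TRUE)
  set.seed(123)
  starts <- fin[sample(nrow(fin), 10), , drop = FALSE]
  for (i in seq_len(nrow(starts))) {
    # agents descending the four-scan chamfer surface stay close to it
    st <- init_simulation(tt_ch, p$lc, cost, starts[i, ], seed = i)
    res <- run_simulation(st)
    expect_true(res$arrived)
    surface_min <- tt_ch$values[starts[i, 1], starts[i, 2]] / 60
    expect_lt(abs(res$elapsed_min - surface_min) / surface_min, 0.10)
    # metrics are consistent by definition
    expect_equal(res$avg_speed_kmh,
                 res$distance_km / (res$elapsed_min / 60))
    # on the exact surface the descent reproduces the surface value and
    # can never undercut it
    st2 <- init_simulation(tt_exact, p$lc, cost, starts[i, ], seed = i)
    res2 <- run_simulation(st2)
    surf2 <- tt_exact$values[starts[i, 1], starts[i, 2]] / 60
    expect_gte(res2$elapsed_min, surf2 - 1e-9)
    expect_equal(res2$elapsed_min, surf2, tolerance = 1e-9)
  }
})

test_that("termination: the patient arrives within the finite-cell step bound", {
  p <- pipeline_fixture()
  cost <- build_cost_grid(p$lc, p$lookup)
  tt <- dijkstra_travel_time(cost, p$dest)
  n_finite <- sum(tt$values < 99999)
  st <- init_simulation(tt, p$lc, cost, c(3, 3), seed = 5)
  res <- run_simulation(st)
  expect_true(res$arrived)
  expect_lte(res$n_steps, n_finite)
})

test_that("pickups occur on road cells only and the mode stays riding to arrival", {
  # cars and the walking patient share the cost grid, so co-location is a
  # phase coincidence; scan fixed seeds and check the mechanism on every
  # run where a pickup happened
  f <- road_plain_fixture()
  n_pickups <- 0
  for (s in 1:20) {
    res <- run_simulation(init_simulation(
      f$tt, f$lc, f$cost, c(5, 10), traffic_intensity = 6, use_cars = TRUE,
      seed = s))
    expect_true(res$arrived)
    if (is.null(res$pickup)) next
    n_pickups <- n_pickups + 1
    pr <- res$pickup$cell
    expect_true(f$lc$values[pr[1], pr[2]] %in% 201:203)
    # after the pickup cell, the trajectory stays on road cells
    traj <- res$trajectory
    k <- which(traj[, 1] == pr[1] & traj[, 2] == pr[2])[1]
    after <- traj[k:nrow(traj), , drop = FALSE]
    expect_true(all(f$lc$values[after] %in% 201:203))
  }
  expect_gt(n_pickups, 0)
})

test_that("higher traffic intensity gives stochastically earlier pickups", {
  f <- road_plain_fixture()
  pickup_time <- function(intensity, seed) {
    res <- run_simulation(init_simulation(
      f$tt, f$lc, f$cost, c(5, 10), traffic_intensity = intensity,
      use_cars = TRUE, seed = seed), max_minutes = 600)
    if (is.null(res$pickup)) 600 * 60 else res$pickup$time
  }
  lo <- vapply(1:50, function(s) pickup_time(0.25, s), numeric(1))
  hi <- vapply(1:50, function(s) pickup_time(2.5, s), numeric(1))
  expect_lt(mean(hi), mean(lo))
})
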