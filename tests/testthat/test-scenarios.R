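test_that("factorial enumeration yields the full cartesian product in axis order", {
  axes3 <- scenario_axes(walking_mode = c("walking", "assisted", "stretcher"),
                         time_of_day = c("day", "night"),
                         weather = c("dry", "rainy", "flooding"))
  specs <- enumerate_scenarios(axes3)
  expect_length(specs, 18)
  # lexicographic: first axis varies slowest
  expect_equal(specs[[1]]$walking_mode, "walking")
  expect_equal(specs[[18]]$walking_mode, "stretcher")
  expect_equal(vapply(specs[1:3], function(s) s$weather, ""),
               c("dry", "rainy", "flooding"))
  # adding a 2-level service axis doubles the matrix
  axes4 <- scenario_axes(walking_mode = c("walking", "assisted", "stretcher"),
                         time_of_day = c("day", "night"),
                         weather = c("dry", "rainy", "flooding"),
                         service = c("doctor_in", "doctor_away"))
  expect_length(enumerate_scenarios(axes4), 36)
  # single-valued axis
  expect_length(enumerate_scenarios(scenario_axes(weather = "dry")), 1)
  # invalid axes rejected
  expect_error(scenario_axes(speed = c("fast")), "unknown scenario field")
  expect_error(scenario_axes(weather = c("dry", "hail")), "invalid value")
})

test_that("base spec fields are inherited by every enumerated scenario", {
  base <- scenario_spec(time_of_day = "night")
  specs <- enumerate_scenarios(scenario_axes(weather = c("dry", "rainy")), base)
  expect_true(all(vapply(specs, function(s) s$time_of_day, "") == "night"))
})

test_that("service availability filters doctor-dependent facilities", {
  dests <- vector_layer(list(
    accesskit:::feature("point", c(100, 100), list(name = "hospital")),
    accesskit:::feature("point", c(200, 200), list(name = "clinic",
                                                   needs_doctor = TRUE))))
  full <- service_availability(scenario_spec(service = "doctor_in"), dests)
  expect_length(full$features, 2)
  away <- service_availability(scenario_spec(service = "doctor_away"), dests)
  expect_length(away$features, 1)
  expect_equal(away$features[[1]]$attributes$name, "hospital")
  only_clinic <- vector_layer(dests$features[2])
  expect_error(service_availability(scenario_spec(service = "doctor_away"),
                                    only_clinic), "no destination")
})

test_that("removing a destination weakly increases travel times everywhere", {
  p <- pipeline_fixture()
  cost <- build_cost_grid(p$lc, p$lookup)
  both <- dijkstra_travel_time(cost, p$dest)
  one <- dijkstra_travel_time(cost, p$dest[1, , drop = FALSE])
  expect_true(all(one$values >= both$values - 1e-9))
})

test_that("a sweep produces one grid pair per spec with dominance across severity", {
  p <- pipeline_fixture(seed = 7, n = 60)
  outdir <- withr::local_tempdir()
  axes <- scenario_axes(time_of_day = c("day", "night"),
                        weather = c("dry", "rainy"))
  mat <- run_sweep(p$lc, p$lookup, p$zones, axes,
                   destinations = p$fx$destinations, engine = "dijkstra",
                   outdir = outdir,
                   composite = file.path(outdir, "matrix.png"))
  expect_length(mat$specs, 4)
  expect_length(list.files(outdir, pattern = "^tt__.*\\.asc$"), 4)
  expect_length(list.files(outdir, pattern = "^zones__.*\\.asc$"), 4)
  expect_true(file.exists(file.path(outdir, "matrix.png")))

  # pairwise dominance: for fixed weather, night >= day everywhere
  find_run <- function(tod, wx) {
    i <- which(vapply(mat$specs, function(s)
      s$time_of_day == tod && s$weather == wx, logical(1)))
    mat$travel_times[[i]]$values
  }
  for (wx in c("dry", "rainy")) {
    expect_true(all(find_run("night", wx) >= find_run("day", wx) - 1e-9))
  }
  # for fixed time, rainy >= dry everywhere
  for (tod in c("day", "night")) {
    expect_true(all(find_run(tod, "rainy") >= find_run(tod, "dry") - 1e-9))
  }
})

test_that("walking-mode severity is pointwise ordered on a fixture", {
  p <- pipeline_fixture(seed = 7, n = 60)
  tt_for <- function(mode) {
    cost <- build_cost_grid(p$lc, p$lookup, scenario_spec(walking_mode = mode))
    dijkstra_travel_time(cost, snap_destinations(p$fx$destinations, p$lc))$values
  }
  w <- tt_for("walking"); a <- tt_for("assisted"); s <- tt_for("stretcher")
  expect_true(all(a >= w - 1e-9))
  expect_true(all(s >= a - 1e-9))
})

test_that("a failing scenario aborts the sweep naming the offending spec", {
  p <- pipeline_fixture(seed = 7, n = 60)
  # destinations that all require the doctor: doctor_away scenarios fail
  dests <- vector_layer(list(accesskit:::feature(
    "point", accesskit::cell_to_xy(p$lc, p$dest[1, 1], p$dest[1, 2]),
    list(needs_doctor = TRUE))))
  axes <- scenario_axes(service = c("doctor_in", "doctor_away"))
  expect_error(
    run_sweep(p$lc, p$lookup, p$zones, axes, destinations = dests,
              engine = "dijkstra"),
    "service=doctor_away")
})
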