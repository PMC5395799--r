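# Raster-network geo-simulation: a patient agent descends the accumulated
# travel-time surface toward the destination, keeps walking when it reaches
# a road, and rides with the first car that shares its cell; cars travel
# road cells only, always toward a destination. Event-driven time: every
# move costs its cell-pair seconds.

#' Initialise a patient-transport simulation
#'
#' @param tt `travel_time_grid` (accumulated seconds; the surface the
#'   patient descends).
#' @param lc land-cover [raster_grid()] (road cells are classes 201-203).
#' @param cost `cost_grid` used for walking move times.
#' @param patient_cell integer `c(row, col)` start cell; must hold a finite
#'   travel time.
#' @param traffic_intensity expected car arrivals per minute (>= 0).
#' @param use_cars enable car agents.
#' @param seed integer seed; trajectories are fully deterministic per seed.
#' @param dest optional `destination_set`; defaults to the zero cells of
#'   `tt`.
#' @return an object of class `simulation_state`.
#' @export
init_simulation <- function(tt, lc, cost, patient_cell, traffic_intensity = 0,
                            use_cars = FALSE, seed = 1, dest = NULL) {
  check_coregistered(tt, lc, cost)
  if (traffic_intensity < 0) stop("traffic_intensity must be >= 0")
  pr <- as.integer(patient_cell[1]); pc <- as.integer(patient_cell[2])
  v <- tt$values[pr, pc]
  if (is.na(v) || v >= SENTINEL)
    stop("patient cell is unreachable (sentinel travel time)")
  if (is.null(dest)) {
    zc <- which(tt$values == 0, arr.ind = TRUE)
    colnames(zc) <- c("row", "col")
    dest <- zc
  }
  road <- !is.na(lc$values) & lc$values %in% 201:203
  # road-constrained travel-time field for car routing: the same exact
  # engine run on a cost grid where everything off-road is a barrier
  road_tt <- NULL
  if (use_cars && any(road)) {
    rcost <- cost$values
    rcost[!road] <- SENTINEL
    rcg <- grid_like(cost, rcost)
    road_dest <- nearest_road_cells(dest, road)
    road_tt <- dijkstra_travel_time(rcg, road_dest)
  }
  state <- list(tt = tt, lc = lc, cost = cost, road = road,
                road_tt = road_tt, dest = dest,
                patient = list(cell = c(pr, pc), mode = "walking",
                               elapsed = 0, metres = 0,
                               path = list(c(pr, pc))),
                cars = list(), use_cars = isTRUE(use_cars),
                traffic_intensity = traffic_intensity,
                next_car_time = NA_real_, seed = seed,
                arrived = all(c(pr, pc) == dest[1, ]) || v == 0,
                pickup = NULL, rng = NULL)
  state <- with_sim_rng(state, {
    if (state$use_cars && traffic_intensity > 0 && !is.null(road_tt))
      state$next_car_time <- stats::rexp(1, rate = traffic_intensity / 60)
    state
  }, init_seed = seed)
  class(state) <- "simulation_state"
  state
}

# Evaluate expr with the state's RNG stream active; capture the stream
# afterwards so the simulation is deterministic per seed and independent
# of the caller's RNG.
with_sim_rng <- function(state, expr, init_seed = NULL) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  if (!is.null(init_seed)) set.seed(init_seed)
  else assign(".Random.seed", state$rng, envir = globalenv())
  res <- force(expr)
  res$rng <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  res
}

nearest_road_cells <- function(dest, road) {
  rc <- which(road, arr.ind = TRUE)
  out <- t(apply(dest, 1, function(d) {
    i <- which.min((rc[, 1] - d[1])^2 + (rc[, 2] - d[2])^2)
    c(rc[i, 1], rc[i, 2])
  }))
  out <- unique(out)
  colnames(out) <- c("row", "col")
  out
}

# One descent step on an accumulated travel-time surface within the
# 16-neighbour move set. Among the passable neighbours with a strictly
# smaller surface value the agent takes the locally time-optimal move, the
# one minimising surface[n] + move seconds (with `cost` given); on a
# consistent surface this follows a shortest-path tree, so walking the
# descent reproduces the surface value at the start cell. Knight moves may
# not jump one-cell barriers. Returns NULL when no smaller neighbour exists.
descend_step <- function(surface, cell, cost = NULL, passable = NULL) {
  nr <- nrow(surface); nc <- ncol(surface)
  if (is.null(passable)) passable <- !is.na(surface) & surface < SENTINEL
  rr <- cell[1] + MOVES$dr; cc <- cell[2] + MOVES$dc
  ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
  ok[ok] <- passable[cbind(rr[ok], cc[ok])]
  for (k in which(ok & MOVES$dist > 2)) {
    m <- knight_mids(MOVES$dr[k], MOVES$dc[k])
    if (!passable[cell[1] + m[1, 1], cell[2] + m[1, 2]] ||
        !passable[cell[1] + m[2, 1], cell[2] + m[2, 2]]) ok[k] <- FALSE
  }
  vals <- rep(Inf, nrow(MOVES))
  vals[ok] <- surface[cbind(rr[ok], cc[ok])]
  vals[is.na(vals)] <- Inf
  here <- surface[cell[1], cell[2]]
  cand <- vals < here
  if (!any(cand)) return(NULL)
  secs <- rep(Inf, nrow(MOVES))
  if (!is.null(cost)) {
    secs[cand] <- MOVES$dist[cand] *
      (cost[cell[1], cell[2]] + cost[cbind(rr[cand], cc[cand])]) / 2
    score <- ifelse(cand, vals + secs, Inf)
  } else {
    score <- ifelse(cand, vals, Inf)
  }
  k <- which.min(score)
  list(cell = c(rr[k], cc[k]), dist_cells = MOVES$dist[k],
       secs = if (is.null(cost)) NA_real_ else secs[k])
}

# Precompute a car's route (cells, entry times in seconds from spawn) by
# descending the road travel-time field from a spawn cell.
car_route <- function(state, spawn_cell) {
  cells <- list(spawn_cell)
  times <- 0
  cur <- spawn_cell
  cost <- state$cost$values
  on_road <- state$road & !is.na(cost) & cost < SENTINEL
  repeat {
    stp <- descend_step(state$road_tt$values, cur, cost, on_road)
    if (is.null(stp)) break
    times <- c(times, times[length(times)] + stp$secs)
    cells[[length(cells) + 1L]] <- stp$cell
    cur <- stp$cell
    if (length(cells) > length(cost)) stop("car route failed to terminate")
  }
  list(cells = cells, times = times)
}

# Spawn cells: road cells on the grid boundary with a finite road field
# value (cars enter from outside the extent).
car_spawn_cells <- function(state) {
  road <- state$road
  nr <- nrow(road); nc <- ncol(road)
  b <- matrix(FALSE, nr, nc)
  b[1, ] <- TRUE; b[nr, ] <- TRUE; b[, 1] <- TRUE; b[, nc] <- TRUE
  ok <- road & b & !is.na(state$road_tt$values) &
    state$road_tt$values < SENTINEL
  which(ok, arr.ind = TRUE)
}

#' Advance the simulation by one patient move
#'
#' The patient moves to the 16-neighbour with the smallest accumulated
#' travel time, paying the cell-pair move cost in seconds. On road cells
#' the patient keeps walking but is picked up by any car sharing its cell
#' during its stay; after pickup the patient rides the car's route to the
#' destination at road speeds.
#'
#' @param state a `simulation_state`.
#' @return the advanced state.
#' @export
step <- function(state) UseMethod("step")

#' @export
step.simulation_state <- function(state) {
  if (state$arrived) return(state)
  p <- state$patient
  cs <- state$tt$cell_size

  if (p$mode == "riding") {
    # follow the car's remaining route one cell at a time
    ride <- state$ride
    i <- ride$i + 1L
    prev <- ride$route$cells[[ride$i]]
    cur <- ride$route$cells[[i]]
    d <- sqrt(sum((cur - prev)^2))
    p$elapsed <- p$elapsed + (ride$route$times[i] - ride$route$times[ride$i])
    p$metres <- p$metres + d * cs
    p$cell <- cur
    p$path[[length(p$path) + 1L]] <- cur
    state$ride$i <- i
    state$patient <- p
    if (i == length(ride$route$cells)) {
      # end of road route; walk any residual descent
      p$mode <- "walking"
      state$patient <- p
      if (state$tt$values[cur[1], cur[2]] == 0) state$arrived <- TRUE
    }
    return(state)
  }

  stp <- descend_step(state$tt$values, p$cell, state$cost$values)
  if (is.null(stp))
    stop("no smaller neighbour on the travel-time surface (inconsistent surface)")
  dt <- stp$secs
  t0 <- p$elapsed
  t1 <- p$elapsed + dt

  # While walking out of the current cell over [t0, t1) the patient can be
  # met by a car sharing that cell (the patient keeps walking on roads
  # rather than standing still; pickup = co-location).
  if (state$use_cars && !is.null(state$road_tt) &&
      state$road[p$cell[1], p$cell[2]]) {
    state <- spawn_cars_until(state, t1)
    pk <- find_pickup(state, p$cell, t0, t1)
    if (!is.null(pk)) {
      state$pickup <- list(cell = p$cell, time = pk$time)
      state$ride <- list(route = pk$route, i = pk$i)
      p$mode <- "riding"
      p$elapsed <- pk$time
      state$patient <- p
      return(state)
    }
  } else if (state$use_cars && !is.null(state$road_tt)) {
    state <- spawn_cars_until(state, t1)
  }

  p$elapsed <- t1
  p$metres <- p$metres + stp$dist_cells * cs
  p$cell <- stp$cell
  p$path[[length(p$path) + 1L]] <- stp$cell
  state$patient <- p
  if (state$tt$values[p$cell[1], p$cell[2]] == 0) state$arrived <- TRUE
  state
}

spawn_cars_until <- function(state, t_end) {
  if (!state$use_cars || state$traffic_intensity <= 0 ||
      is.na(state$next_car_time)) return(state)
  spawns <- car_spawn_cells(state)
  if (!nrow(spawns)) return(state)
  while (!is.na(state$next_car_time) && state$next_car_time <= t_end) {
    t_spawn <- state$next_car_time
    state <- with_sim_rng(state, {
      i <- sample.int(nrow(spawns), 1)
      route <- car_route(state, c(spawns[i, 1], spawns[i, 2]))
      state$cars[[length(state$cars) + 1L]] <-
        list(spawn_time = t_spawn, route = route)
      state$next_car_time <- t_spawn +
        stats::rexp(1, rate = state$traffic_intensity / 60)
      state
    })
  }
  state
}

# Does any car stand on `cell` during (t0, t1]? Cars occupy route cell i
# over [spawn + times[i], spawn + times[i+1]); the last cell forever (the
# car has arrived; treat as gone -> exclude final cell).
find_pickup <- function(state, cell, t0, t1) {
  best <- NULL
  for (car in state$cars) {
    route <- car$route
    n <- length(route$cells)
    for (i in seq_len(max(0, n - 1))) {
      rc <- route$cells[[i]]
      if (rc[1] != cell[1] || rc[2] != cell[2]) next
      enter <- car$spawn_time + route$times[i]
      leave <- car$spawn_time + route$times[i + 1]
      if (enter < t1 && leave > t0) {
        t_meet <- max(t0, enter)
        if (is.null(best) || t_meet < best$time)
          best <- list(time = t_meet, route = route, i = i)
      }
    }
  }
  best
}

#' Run the simulation to arrival or time-out
#'
#' @param state a `simulation_state` from [init_simulation()].
#' @param max_minutes wall-clock cap in simulated minutes (> 0).
#' @return an object of class `simulation_result` with fields `arrived`,
#'   `elapsed_min`, `distance_km`, `avg_speed_kmh`, `pickup` (list or
#'   `NULL`), `trajectory` (matrix of row, col), `n_steps`.
#' @export
run_simulation <- function(state, max_minutes = 24 * 60) {
  if (max_minutes <= 0) stop("max_minutes must be > 0")
  max_steps <- 4L * sum(!is.na(state$tt$values) &
                          state$tt$values < SENTINEL) + 8L
  n <- 0L
  while (!state$arrived && state$patient$elapsed / 60 < max_minutes) {
    state <- step(state)
    n <- n + 1L
    if (n > max_steps)
      stop("simulation failed to terminate within the step bound")
  }
  p <- state$patient
  elapsed_min <- p$elapsed / 60
  distance_km <- p$metres / 1000
  structure(list(
    arrived = state$arrived,
    elapsed_min = elapsed_min,
    distance_km = distance_km,
    avg_speed_kmh = if (elapsed_min > 0) distance_km / (elapsed_min / 60)
                    else 0,
    pickup = state$pickup,
    trajectory = do.call(rbind, p$path),
    n_steps = n,
    state = state), class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("simulation: %s in %.1f min, %.2f km, %.1f km/h%s\n",
              if (x$arrived) "arrived" else "timed out",
              x$elapsed_min, x$distance_km, x$avg_speed_kmh,
              if (!is.null(x$pickup))
                sprintf(" (picked up at %.1f min)", x$pickup$time / 60)
              else " (walked)"))
  invisible(x)
}
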