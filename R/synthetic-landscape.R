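# Seeded synthetic landscapes (DEM, vegetation, roads, destinations) with
# the structure the pipeline assumes, so every downstream module runs
# without any external data.

# Smooth correlated random field on an nr x nc grid: coarse white noise
# upsampled bilinearly. Cheap, deterministic and band-limited, which is all
# the generators need.
smooth_field <- function(nr, nc, coarse = 8) {
  cr <- max(2, ceiling(nr / coarse)) + 1
  cc <- max(2, ceiling(nc / coarse)) + 1
  z <- matrix(stats::rnorm(cr * cc), cr, cc)
  # one smoothing pass on the coarse grid softens upsampling artefacts
  zs <- z
  for (i in 2:(cr - 1)) for (j in 2:(cc - 1))
    zs[i, j] <- mean(z[(i - 1):(i + 1), (j - 1):(j + 1)])
  bilinear_upsample(zs, nr, nc)
}

bilinear_upsample <- function(z, nr, nc) {
  cr <- nrow(z); cc <- ncol(z)
  ry <- seq(1, cr, length.out = nr)
  cx <- seq(1, cc, length.out = nc)
  r0 <- pmin(floor(ry), cr - 1); c0 <- pmin(floor(cx), cc - 1)
  fy <- ry - r0; fx <- cx - c0
  out <- matrix(0, nr, nc)
  for (j in seq_len(nc)) {
    jc <- c0[j]; f <- fx[j]
    col0 <- z[, jc] * (1 - f) + z[, jc + 1] * f
    out[, j] <- col0[r0] * (1 - fy) + col0[r0 + 1] * fy
  }
  out
}

#' Generate a synthetic DEM
#'
#' A smooth correlated noise field superimposed on a central dome, so the
#' terrain mostly drains outward to the grid edge and Strahler ordering
#' yields a multi-order stream network. Deterministic per seed.
#'
#' @param seed integer seed.
#' @param n_rows,n_cols grid dimensions (>= 16).
#' @param relief_m total relief in metres (> 0); default 120.
#' @param cell_size cell size in metres; default 50 (the demonstration
#'   configuration uses a 30 x 30 km extent of 50 m cells).
#' @return a [raster_grid()] of elevations.
#' @export
generate_dem <- function(seed, n_rows = 600, n_cols = 600, relief_m = 120,
                         cell_size = 50) {
  if (n_rows < 16 || n_cols < 16) stop("DEM dimensions must be >= 16")
  if (relief_m <= 0) stop("relief_m must be > 0")
  withr_seed(seed, {
    noise <- smooth_field(n_rows, n_cols)
    noise <- (noise - min(noise)) / diff(range(noise))
    r <- (row(noise) - (n_rows + 1) / 2) / (n_rows / 2)
    c <- (col(noise) - (n_cols + 1) / 2) / (n_cols / 2)
    dome <- 1 - sqrt(r^2 + c^2) / sqrt(2)
    z <- relief_m * (0.65 * dome + 0.35 * noise)
    raster_grid(z, cell_size)
  })
}

# Run expr with a temporarily seeded RNG, restoring any prior state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic vegetation raster
#'
#' Smooth-noise field cut at fixed quantiles into four contiguous-patch
#' classes: 1 = Forest, 2 = Grass, 3 = Bare, 4 = Scrub. Elevation nudges
#' the field so forest favours low ground and bare/rocky cover high ground.
#'
#' @param seed integer seed.
#' @param dem a [raster_grid()] supplying geometry and elevations.
#' @return a [raster_grid()] with values in \{1, 2, 3, 4\}.
#' @export
generate_vegetation <- function(seed, dem) {
  stopifnot(is_raster_grid(dem))
  withr_seed(seed + 1L, {
    f <- smooth_field(n_rows(dem), n_cols(dem), coarse = 6)
    zn <- dem$values
    zn <- (zn - min(zn, na.rm = TRUE)) /
      max(1e-9, diff(range(zn, na.rm = TRUE)))
    field <- f + 1.2 * zn
    q <- stats::quantile(field, c(0.35, 0.6, 0.8), na.rm = TRUE)
    veg <- matrix(1L, n_rows(dem), n_cols(dem))
    veg[field >= q[1]] <- 2L
    veg[field >= q[2]] <- 4L
    veg[field >= q[3]] <- 3L
    veg[is.na(dem$values)] <- NA_integer_
    grid_like(dem, veg)
  })
}

#' Generate a synthetic road network
#'
#' One national trunk road crossing the full extent west to east, two
#' provincial branches running toward the north and south edges, and local
#' spurs off the branches. Vertices are jittered per seed and clipped to
#' the extent.
#'
#' @param seed integer seed.
#' @param grid_spec a [raster_grid()] defining the extent.
#' @return a [vector_layer()] of polylines with a `class` attribute in
#'   \{national, provincial, local\}.
#' @export
generate_roads <- function(seed, grid_spec) {
  stopifnot(is_raster_grid(grid_spec))
  withr_seed(seed + 2L, {
    W <- n_cols(grid_spec) * grid_spec$cell_size
    H <- n_rows(grid_spec) * grid_spec$cell_size
    x0 <- grid_spec$origin_x; y0 <- grid_spec$origin_y
    clip <- function(m) {
      m[, 1] <- pmin(pmax(m[, 1], x0 + 1e-6), x0 + W - 1e-6)
      m[, 2] <- pmin(pmax(m[, 2], y0 + 1e-6), y0 + H - 1e-6)
      m
    }
    # national trunk: west -> east with gentle wiggle around mid-height
    nx <- 9
    tx <- x0 + seq(0, W, length.out = nx)
    ty <- y0 + H * (0.5 + 0.08 * sin(seq(0, pi, length.out = nx)) +
                      stats::rnorm(nx, 0, 0.02))
    trunk <- clip(cbind(tx, ty))
    feats <- list(feature("linestring", trunk, list(class = "national", name = "trunk")))
    # provincial branches leave the trunk at 1/3 and 2/3
    for (i in 1:2) {
      bx <- trunk[c(3, 7)[i], 1]
      by <- trunk[c(3, 7)[i], 2]
      sgn <- if (i == 1) 1 else -1
      k <- 5
      px <- bx + cumsum(c(0, stats::rnorm(k - 1, 0, W * 0.02)))
      py <- seq(by, y0 + H * (0.5 + sgn * 0.45), length.out = k)
      branch <- clip(cbind(px, py))
      feats[[length(feats) + 1L]] <-
        feature("linestring", branch,
                list(class = "provincial", name = paste0("branch", i)))
      # one local spur off the middle of each branch
      sx <- branch[3, 1]; sy <- branch[3, 2]
      spur <- clip(cbind(sx + seq(0, sgn * W * 0.12, length.out = 4) +
                           stats::rnorm(4, 0, W * 0.01),
                         sy + stats::rnorm(4, 0, H * 0.015)))
      spur[1, ] <- c(sx, sy)
      feats[[length(feats) + 1L]] <-
        feature("linestring", spur,
                list(class = "local", name = paste0("spur", i)))
    }
    vector_layer(feats)
  })
}

#' Generate destination points
#'
#' `k` facility points placed on the national trunk road (so both walking
#' and vehicle journeys can terminate there), evenly spaced along it.
#' Each destination carries a `name` and a logical `needs_doctor`
#' attribute (every second facility depends on the visiting doctor being
#' in) for service-availability scenarios.
#'
#' @param seed integer seed.
#' @param k number of destinations (>= 1).
#' @param grid_spec a [raster_grid()] defining the extent.
#' @param roads optional [vector_layer()] from [generate_roads()]; when
#'   omitted it is regenerated from the same seed.
#' @return a [vector_layer()] of points.
#' @export
generate_destinations <- function(seed, k = 2, grid_spec, roads = NULL) {
  if (k < 1) stop("k must be >= 1")
  if (is.null(roads)) roads <- generate_roads(seed, grid_spec)
  trunk <- NULL
  for (f in roads$features)
    if (identical(f$attributes$class, "national")) { trunk <- f$coords; break }
  if (is.null(trunk)) stop("road layer has no national trunk road")
  # arc-length positions at fractions 1/(k+1) .. k/(k+1) along the trunk
  seg <- sqrt(diff(trunk[, 1])^2 + diff(trunk[, 2])^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  feats <- lapply(seq_len(k), function(i) {
    target <- total * i / (k + 1)
    j <- findInterval(target, s, rightmost.closed = TRUE)
    j <- min(j, length(seg))
    f <- (target - s[j]) / seg[j]
    pt <- trunk[j, ] + f * (trunk[j + 1, ] - trunk[j, ])
    feature("point", matrix(pt, ncol = 2),
            list(name = paste0("facility", i),
                 needs_doctor = (i %% 2 == 0)))
  })
  vector_layer(feats)
}

#' Generate a complete synthetic landscape fixture
#'
#' @param seed integer seed.
#' @param n_rows,n_cols grid dimensions; the demonstration default is
#'   600 x 600 at 50 m (a 30 x 30 km extent).
#' @param cell_size cell size in metres.
#' @param relief_m DEM relief in metres.
#' @param k_destinations number of facility points.
#' @return a list with elements `dem`, `vegetation`, `roads`,
#'   `destinations`, `seed`, of class `landscape_fixture`.
#' @export
generate_landscape <- function(seed, n_rows = 600, n_cols = 600,
                               cell_size = 50, relief_m = 120,
                               k_destinations = 2) {
  dem <- generate_dem(seed, n_rows, n_cols, relief_m, cell_size)
  veg <- generate_vegetation(seed, dem)
  roads <- generate_roads(seed, dem)
  dest <- generate_destinations(seed, k_destinations, dem, roads)
  structure(list(dem = dem, vegetation = veg, roads = roads,
                 destinations = dest, seed = seed),
            class = "landscape_fixture")
}
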