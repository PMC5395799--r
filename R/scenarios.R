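# Factorial scenario sweeps: enumerate the cartesian product of scenario
# axes, run travel time + zoning for each combination, lay the results out
# worst-to-best.

AXIS_LEVELS <- list(
  walking_mode = c("walking", "assisted", "stretcher"),
  time_of_day = c("day", "night"),
  weather = c("dry", "rainy", "flooding"),
  service = c("doctor_in", "doctor_away"))

#' Scenario axes for a factorial sweep
#'
#' @param ... named axes; each name a [scenario_spec()] field among
#'   `walking_mode`, `time_of_day`, `weather`, `service`, each value a
#'   non-empty vector of levels valid for that field.
#' @return an object of class `scenario_axes`.
#' @export
scenario_axes <- function(...) {
  axes <- list(...)
  if (length(axes) == 1 && is.list(axes[[1]]) && is.null(names(axes)[1]))
    axes <- axes[[1]]
  if (!length(axes) || is.null(names(axes)) || any(!nzchar(names(axes))))
    stop("axes must be named")
  for (nm in names(axes)) {
    if (!nm %in% names(AXIS_LEVELS))
      stop(sprintf("unknown scenario field '%s'; valid axes: %s", nm,
                   paste(names(AXIS_LEVELS), collapse = ", ")))
    if (!length(axes[[nm]])) stop(sprintf("axis '%s' is empty", nm))
    bad <- setdiff(axes[[nm]], AXIS_LEVELS[[nm]])
    if (length(bad))
      stop(sprintf("invalid value(s) for axis '%s': %s", nm,
                   paste(bad, collapse = ", ")))
  }
  structure(axes, class = "scenario_axes")
}

#' Enumerate the full cartesian product of scenario axes
#'
#' Returns one [scenario_spec()] per combination, in lexicographic order
#' over the axes as given (the first axis varies slowest); `base` supplies
#' every unlisted field.
#'
#' @param axes a [scenario_axes()].
#' @param base a [scenario_spec()] giving defaults for unlisted fields.
#' @return list of `scenario_spec`, length = product of axis sizes.
#' @export
enumerate_scenarios <- function(axes, base = scenario_spec()) {
  stopifnot(inherits(axes, "scenario_axes"), inherits(base, "scenario_spec"))
  grid <- expand.grid(rev(lapply(axes, as.character)),
                      stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(axes)), drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i) {
    s <- unclass(base)
    for (nm in names(axes)) s[[nm]] <- grid[i, nm]
    do.call(scenario_spec, s)
  })
}

# Severity rank of a spec (higher = worse travel conditions): sum of
# per-axis ranks. Defines the worst-to-best composite ordering.
scenario_severity <- function(spec) {
  sum(vapply(names(AXIS_LEVELS), function(nm)
    match(spec[[nm]], AXIS_LEVELS[[nm]]), numeric(1)))
}

scenario_label <- function(spec, axes_names = names(AXIS_LEVELS)) {
  paste(vapply(axes_names, function(nm) paste0(nm, "=", spec[[nm]]),
               character(1)), collapse = "__")
}

#' Filter destinations by service availability
#'
#' Destinations may carry a logical `needs_doctor` attribute; those
#' facilities are unavailable when the scenario's service factor is
#' `doctor_away`.
#'
#' @param spec a [scenario_spec()].
#' @param destinations a [vector_layer()] of points.
#' @return the available subset as a [vector_layer()]; error if none.
#' @export
service_availability <- function(spec, destinations) {
  stopifnot(inherits(spec, "scenario_spec"),
            inherits(destinations, "vector_layer"))
  if (spec$service == "doctor_in") return(destinations)
  keep <- Filter(function(f) !isTRUE(f$attributes$needs_doctor),
                 destinations$features)
  if (!length(keep))
    stop("no destination offers service under this scenario (doctor away)")
  vector_layer(keep)
}

#' Run a factorial scenario sweep
#'
#' One travel-time grid and one zone grid per enumerated scenario, with
#' optional per-scenario `.asc` outputs and a tiled composite image laid
#' out worst travel conditions first.
#'
#' @param lc land-cover [raster_grid()].
#' @param lookup a `speed_lookup`.
#' @param zones a `zone_table`.
#' @param axes a [scenario_axes()].
#' @param base base [scenario_spec()]; must carry `destinations`.
#' @param destinations a [vector_layer()] of points (overrides
#'   `base$destinations` when given).
#' @param engine `"chamfer"` or `"dijkstra"`.
#' @param outdir optional directory for per-scenario grids
#'   (`tt__<axis>=<value>__...asc`, `zones__...asc`).
#' @param composite optional PNG path for the tiled zone-map matrix.
#' @return an object of class `scenario_matrix`: list with `specs`,
#'   `travel_times`, `zone_grids`, `severity`, `labels`.
#' @export
run_sweep <- function(lc, lookup, zones, axes, base = scenario_spec(),
                      destinations = NULL, engine = c("chamfer", "dijkstra"),
                      outdir = NULL, composite = NULL) {
  engine <- match.arg(engine)
  dest_layer <- if (!is.null(destinations)) destinations else base$destinations
  if (is.null(dest_layer)) stop("no destinations supplied for the sweep")
  specs <- enumerate_scenarios(axes, base)
  tts <- vector("list", length(specs))
  zgs <- vector("list", length(specs))
  labels <- character(length(specs))
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    labels[i] <- scenario_label(spec, names(axes))
    res <- tryCatch({
      avail <- service_availability(spec, dest_layer)
      dest <- snap_destinations(avail, lc)
      cost <- build_cost_grid(lc, lookup, spec)
      tt <- if (engine == "chamfer") chamfer_travel_time(cost, dest)
            else dijkstra_travel_time(cost, dest)
      list(tt = tt, zg = classify_zones(tt, zones))
    }, error = function(e)
      stop(sprintf("sweep aborted at scenario [%s]: %s", labels[i],
                   conditionMessage(e)), call. = FALSE))
    tts[[i]] <- res$tt
    zgs[[i]] <- res$zg
    if (!is.null(outdir)) {
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      safe <- gsub("[^A-Za-z0-9_=.-]", "-", labels[i])
      write_ascii_grid(res$tt, file.path(outdir, paste0("tt__", safe, ".asc")))
      write_ascii_grid(res$zg, file.path(outdir, paste0("zones__", safe, ".asc")))
    }
  }
  sev <- vapply(specs, scenario_severity, numeric(1))
  out <- structure(list(specs = specs, travel_times = tts, zone_grids = zgs,
                        severity = sev, labels = labels, axes = axes),
                   class = "scenario_matrix")
  if (!is.null(composite)) plot_scenario_matrix(out, composite)
  out
}

#' @export
print.scenario_matrix <- function(x, ...) {
  cat(sprintf("scenario_matrix: %d runs over axes %s\n", length(x$specs),
              paste(names(x$axes), collapse = " x ")))
  invisible(x)
}

#' Write the tiled composite zone-map image
#'
#' Tiles the sweep's zone maps in decreasing severity (worst travel
#' conditions at the top left).
#'
#' @param matrix a `scenario_matrix` from [run_sweep()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
plot_scenario_matrix <- function(matrix, path) {
  ord <- order(-matrix$severity, matrix$labels)
  n <- length(ord)
  ncol_t <- ceiling(sqrt(n))
  nrow_t <- ceiling(n / ncol_t)
  zone_cols <- c("#08306b", "#4292c6", "#41ab5d", "#fee391", "#fe9929",
                 "#cb181d")
  grDevices::png(path, width = 240 * ncol_t, height = 240 * nrow_t)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(nrow_t, ncol_t), mar = c(0.5, 0.5, 2, 0.5))
  for (i in ord) {
    z <- matrix$zone_grids[[i]]$values
    graphics::image(t(z[nrow(z):1, , drop = FALSE]), col = zone_cols,
                    zlim = c(1, 6), axes = FALSE,
                    main = matrix$labels[i], cex.main = 0.7)
  }
  invisible(path)
}
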