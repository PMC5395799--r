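# Readers and writers for every external format the toolkit touches:
# ESRI ASCII grid for rasters, GeoJSON for points/polylines, CSV for the
# speed and zone lookup tables, YAML for scenario configs.

ROAD_CLASSES <- c(national = 201L, provincial = 202L, local = 203L)
VEG_CLASSES <- c(Forest = 1L, Grass = 2L, Bare = 3L, Scrub = 4L)
STREAM_CLASS_IDS <- 101:105
LANDCOVER_IDS <- c(1:4, 101:105, 201:203)

num_str <- function(x) {
  # Canonical, locale-independent number formatting (what base R prints for
  # a double, up to 15 significant digits); makes write(read(f)) == f
  # byte-comparable for files the writer itself produced.
  vapply(x, function(v) format(v, scientific = FALSE, trim = TRUE,
                               digits = 15), character(1))
}

#' Read an ESRI ASCII grid
#'
#' Parses the six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`; the last optional) followed by row-major
#' values from the north edge. Cells equal to the nodata sentinel become
#' `NA`.
#'
#' @param path file path.
#' @return a [raster_grid()].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6) stop("malformed ASCII grid: fewer than 6 lines")
  hdr <- list()
  i <- 1
  while (i <= length(lines)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) == 2 &&
        tolower(parts[1]) %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                                 "cellsize", "nodata_value")) {
      val <- suppressWarnings(as.numeric(parts[2]))
      if (is.na(val))
        stop(sprintf("malformed ASCII grid header line: '%s'", lines[i]))
      hdr[[tolower(parts[1])]] <- val
      i <- i + 1
    } else break
  }
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[k]]))
      stop(sprintf("malformed ASCII grid header: missing '%s'", k))
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  body <- lines[i:length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != nr)
    stop(sprintf("malformed ASCII grid: expected %d data rows, found %d",
                 nr, length(body)))
  rows <- lapply(seq_along(body), function(j) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(body[j]), "\\s+")[[1]]))
    if (length(v) != nc || anyNA(v))
      stop(sprintf("malformed ASCII grid: row %d has inconsistent length or non-numeric values", j))
    v
  })
  values <- do.call(rbind, rows)
  values[values == nodata] <- NA
  raster_grid(values, hdr$cellsize, hdr$xllcorner, hdr$yllcorner, nodata)
}

#' Write an ESRI ASCII grid
#'
#' Canonical formatting: lower-case header keys, one grid row per line from
#' the north edge, `NA` cells written as the grid's nodata sentinel.
#'
#' @param grid a [raster_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(is_raster_grid(grid))
  v <- grid$values
  v[is.na(v)] <- grid$nodata
  hdr <- c(
    paste("ncols", n_cols(grid)),
    paste("nrows", n_rows(grid)),
    paste("xllcorner", num_str(grid$origin_x)),
    paste("yllcorner", num_str(grid$origin_y)),
    paste("cellsize", num_str(grid$cell_size)),
    paste("NODATA_value", num_str(grid$nodata)))
  body <- apply(v, 1, function(r) paste(num_str(r), collapse = " "))
  con <- file(path, "wb")  # fixed "\n" endings regardless of platform
  on.exit(close(con))
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(path)
}

#' Vector layer of points or polylines
#'
#' A light container: a list of features, each holding a geometry type
#' (`"point"` or `"linestring"`), a coordinate matrix in map units, and a
#' named attribute list.
#'
#' @param features list of `list(type =, coords =, attributes =)` entries.
#' @return an object of class `vector_layer`.
#' @export
vector_layer <- function(features = list()) {
  structure(list(features = features), class = "vector_layer")
}

#' @export
print.vector_layer <- function(x, ...) {
  types <- vapply(x$features, `[[`, character(1), "type")
  cat(sprintf("vector_layer: %d features (%s)\n", length(x$features),
              paste(sprintf("%d %s", table(types), names(table(types))),
                    collapse = ", ")))
  invisible(x)
}

feature <- function(type, coords, attributes = list()) {
  coords <- matrix(as.numeric(coords), ncol = 2)
  list(type = type, coords = coords, attributes = attributes)
}

#' Read a GeoJSON FeatureCollection of points or linestrings
#'
#' Attributes are preserved. Road features (any feature carrying a `class`
#' property) are validated against the allowed classes
#' `national`, `provincial`, `local`.
#'
#' @param path GeoJSON file.
#' @return a [vector_layer()].
#' @export
read_vector <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection")
  feats <- lapply(gj$features, function(f) {
    geom <- f$geometry
    typ <- tolower(geom$type)
    if (!typ %in% c("point", "linestring"))
      stop(sprintf("unsupported geometry type '%s'", geom$type))
    coords <- if (typ == "point") {
      matrix(unlist(geom$coordinates), ncol = 2)
    } else {
      do.call(rbind, lapply(geom$coordinates, unlist))
    }
    attrs <- if (is.null(f$properties)) list() else f$properties
    if (!is.null(attrs$class) &&
        !attrs$class %in% names(ROAD_CLASSES))
      stop(sprintf(
        "unknown road class '%s'; allowed values: %s", attrs$class,
        paste(names(ROAD_CLASSES), collapse = ", ")))
    feature(typ, coords, attrs)
  })
  vector_layer(feats)
}

#' Write a vector layer as GeoJSON
#' @param layer a [vector_layer()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vector <- function(layer, path) {
  feats <- lapply(layer$features, function(f) {
    coords <- if (f$type == "point") {
      as.numeric(f$coords[1, ])
    } else {
      lapply(seq_len(nrow(f$coords)), function(i) as.numeric(f$coords[i, ]))
    }
    list(type = "Feature",
         geometry = list(
           type = if (f$type == "point") "Point" else "LineString",
           coordinates = coords),
         properties = if (length(f$attributes)) f$attributes else
           structure(list(), names = character(0)))
  })
  out <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read the land-cover speed lookup table
#'
#' CSV with columns `id`, `cover_class`, `kmh`. Every id of the twelve-class
#' land-cover schema (1-4 vegetation, 101-105 stream orders, 201-203 roads)
#' must be present exactly once. Per-cell traversal seconds are derived at
#' use time from km/h and the grid's cell size; a speed of 0 marks the class
#' impassable (99,999 s sentinel).
#'
#' @param path CSV file.
#' @return data frame of class `speed_lookup`.
#' @export
read_lookup_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "cover_class", "kmh")
  if (!all(need %in% names(df)))
    stop("speed lookup must have columns id, cover_class, kmh")
  if (anyDuplicated(df$id))
    stop(sprintf("duplicate class id(s) in speed lookup: %s",
                 paste(unique(df$id[duplicated(df$id)]), collapse = ", ")))
  missing <- setdiff(LANDCOVER_IDS, df$id)
  if (length(missing))
    stop(sprintf("speed lookup missing class id(s): %s",
                 paste(missing, collapse = ", ")))
  if (any(df$kmh < 0)) stop("speeds must be >= 0 km/h")
  df <- df[order(df$id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("speed_lookup", "data.frame")
  df
}

#' Read the travel-time zone table
#'
#' CSV with columns `class`, `min_minutes`, `max_minutes`. Intervals are
#' half-open `[min, max)`, must be ordered, non-overlapping and gap-free,
#' starting at 0.
#'
#' @param path CSV file.
#' @return data frame of class `zone_table`.
#' @export
read_zone_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("class", "min_minutes", "max_minutes")
  if (!all(need %in% names(df)))
    stop("zone table must have columns class, min_minutes, max_minutes")
  df <- df[order(df$min_minutes), , drop = FALSE]
  rownames(df) <- NULL
  if (df$min_minutes[1] != 0) stop("zone table must start at 0 minutes")
  if (any(df$max_minutes <= df$min_minutes))
    stop("zone intervals must have max > min")
  if (nrow(df) > 1) {
    gaps <- df$min_minutes[-1] != df$max_minutes[-nrow(df)]
    if (any(gaps))
      stop("zone intervals must be contiguous (no gaps or overlaps)")
  }
  class(df) <- c("zone_table", "data.frame")
  df
}

#' Path to a packaged default table
#'
#' The package ships the default land-cover speed table (twelve classes,
#' km/h) and the six-band travel-time zone table as CSV, so the standard
#' configuration runs with no authoring.
#'
#' @param name `"speed_table.csv"` or `"zone_table.csv"`.
#' @return file path inside the installed package.
#' @export
accesskit_table <- function(name = c("speed_table.csv", "zone_table.csv")) {
  name <- match.arg(name)
  system.file("extdata", name, package = "accesskit", mustWork = TRUE)
}
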