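# Plain-text interchange: GeoJSON geometries, ESRI ASCII grids, CSV tables.

#' Write lake geometry to GeoJSON
#'
#' One Polygon feature (shoreline with island holes) plus one LineString
#' feature per isobath carrying a `depth_m` property. Coordinates are kept
#' in the planar metric system of the geometry.
#'
#' @param geometry a [lake_geometry()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_lake_geojson <- function(geometry, path) {
  stopifnot(inherits(geometry, "lake_geometry"))
  close_ring <- function(m) unname(.ring_close(m))
  poly <- list(
    type = "Feature",
    properties = list(role = "shoreline", lake_id = geometry$lake_id,
                      z_max = geometry$z_max,
                      lake_area_ha = geometry$lake_area_ha,
                      flat_depth = geometry$flat_depth),
    geometry = list(type = "Polygon",
                    coordinates = c(list(close_ring(geometry$shoreline)),
                                    lapply(geometry$islands, close_ring))))
  isos <- lapply(geometry$isobaths, function(iso) {
    coords <- if (isTRUE(iso$closed)) .ring_close(iso$coords) else iso$coords
    list(type = "Feature",
         properties = list(role = "isobath", depth_m = iso$depth,
                           closed = isTRUE(iso$closed)),
         geometry = list(type = "LineString",
                         coordinates = unname(coords)))
  })
  fc <- list(type = "FeatureCollection", features = c(list(poly), isos))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 10,
                       null = "null")
  invisible(path)
}

#' Read lake geometry from GeoJSON
#'
#' Expects the layout written by [write_lake_geojson()]: a shoreline
#' Polygon and depth-labelled isobath LineStrings.
#'
#' @param path GeoJSON file.
#' @return a [lake_geometry()].
#' @export
read_lake_geojson <- function(path) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(fc$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection")
  to_mat <- function(coords)
    do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
  shoreline <- NULL; islands <- list(); isobaths <- list()
  props <- NULL
  for (f in fc$features) {
    g <- f$geometry
    if (identical(g$type, "Polygon")) {
      shoreline <- to_mat(g$coordinates[[1]])
      if (length(g$coordinates) > 1L)
        islands <- lapply(g$coordinates[-1], to_mat)
      props <- f$properties
    } else if (identical(g$type, "LineString")) {
      isobaths[[length(isobaths) + 1L]] <-
        list(depth = f$properties$depth_m, coords = to_mat(g$coordinates),
             closed = isTRUE(f$properties$closed))
    }
  }
  if (is.null(shoreline)) stop("no shoreline Polygon feature found")
  lake_geometry(shoreline, isobaths = isobaths, islands = islands,
                z_max = props$z_max, flat_depth = props$flat_depth,
                lake_id = if (is.null(props$lake_id)) "lake" else
                  props$lake_id)
}

#' Write a grid as an ESRI ASCII raster
#'
#' @param grid a [depth_grid()] or slope raster.
#' @param path output `.asc` file.
#' @param nodata no-data value, default -9999.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  v <- grid$values
  cs <- grid$cell_size
  header <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.6f", grid$origin[1L] - cs / 2),
    sprintf("yllcorner %.6f", grid$origin[2L] - cs / 2),
    sprintf("cellsize %.6f", cs),
    sprintf("NODATA_value %g", nodata))
  v[is.na(v)] <- nodata
  rows <- apply(v[rev(seq_len(nrow(v))), , drop = FALSE], 1L,
                function(r) paste(formatC(r, format = "g", digits = 10),
                                  collapse = " "))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII raster into a depth grid
#'
#' @param path `.asc` file.
#' @return a [depth_grid()] (no unclipped surface).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  vals <- lapply(lines[i:length(lines)],
                 function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, vals)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  cs <- hdr$cellsize
  depth_grid(c(hdr$xllcorner + cs / 2, hdr$yllcorner + cs / 2), cs, m)
}

#' Write / read an hourly wind series as CSV
#'
#' Columns: ISO-8601 `timestamp` (UTC), `dir_deg`, `speed_ms`.
#'
#' @param wind a `wind_series`.
#' @param path CSV file.
#' @return `path` / a `wind_series`.
#' @export
write_wind_csv <- function(wind, path) {
  rec <- wind$records
  out <- data.frame(
    timestamp = format(rec$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    dir_deg = rec$dir_deg, speed_ms = rec$speed_ms)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_wind_csv
#' @param station_id station identifier for the reconstructed series.
#' @export
read_wind_csv <- function(path, station_id = "CSV") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "dir_deg", "speed_ms")
  if (!all(need %in% names(d)))
    stop("wind CSV needs columns: ", paste(need, collapse = ", "))
  ts <- as.POSIXct(d$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  structure(list(records = data.frame(timestamp = ts, dir_deg = d$dir_deg,
                                      speed_ms = d$speed_ms),
                 station_id = station_id, window = range(ts)),
            class = "wind_series")
}

#' Write / read a survey table as CSV
#'
#' The long cover table and the per-transect info table go to two files.
#'
#' @param survey a `survey_table`.
#' @param data_path CSV for the long cover table.
#' @param info_path CSV for the per-transect info table.
#' @export
write_survey_csv <- function(survey, data_path, info_path) {
  utils::write.csv(survey$data, data_path, row.names = FALSE)
  utils::write.csv(survey$transect_info, info_path, row.names = FALSE)
  invisible(c(data_path, info_path))
}

#' @rdname write_survey_csv
#' @export
read_survey_csv <- function(data_path, info_path) {
  d <- utils::read.csv(data_path, stringsAsFactors = FALSE)
  info <- utils::read.csv(info_path, stringsAsFactors = FALSE)
  need <- c("lake_id", "transect_id", "syntaxon_code", "group",
            "rel_cover_pct")
  if (!all(need %in% names(d)))
    stop("survey CSV needs columns: ", paste(need, collapse = ", "))
  syn <- unique(d[, c("syntaxon_code", "group")])
  rownames(syn) <- NULL
  structure(list(data = d, transect_info = info, syntaxa = syn),
            class = "survey_table")
}
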