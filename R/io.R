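# File I/O: per-hexagon CSV dialects for grids, climates, worlds and
# patterns, a GeoJSON export of grid polygons, and run-metadata records.

#' Write and read a grid as CSV
#'
#' One row per cell with the neighbour list serialised as a
#' semicolon-separated field. The round trip preserves everything needed
#' to re-run a simulation (ids, centroids, areas, hemispheres, adjacency);
#' the geodesic attributes (`xyz`, `triangles`) are rebuilt only by
#' [hex_grid_freq()], so a re-read grid supports simulation but not
#' polygon export.
#'
#' @param grid A `hex_grid`.
#' @param path CSV file path.
#' @return `write_grid_csv()` returns `path` invisibly; `read_grid_csv()`
#'   a `hex_grid` tibble.
#' @export
write_grid_csv <- function(grid, path) {
  d <- as_tibble(grid)
  d$neighbors <- vapply(d$neighbors, paste, character(1), collapse = ";")
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  d <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  d$neighbors <- lapply(strsplit(d$neighbors, ";"), as.integer)
  to_rad <- pi / 180
  xyz <- cbind(cos(d$lat * to_rad) * cos(d$lon * to_rad),
               cos(d$lat * to_rad) * sin(d$lon * to_rad),
               sin(d$lat * to_rad))
  structure(d, class = c("hex_grid", class(tibble())), xyz = xyz,
            freq = as.integer(round(sqrt((nrow(d) - 2) / 10))))
}

#' Write and read the monthly climate table of a world
#'
#' Long CSV with columns `cell_id`, `month`, `temp_c`, `precip_mm`, `npp`,
#' plus the ice mask as a one-column CSV of cell ids. `read_world_csv()`
#' validates the table (all 12 months per cell, plausible units) and
#' assembles a `world` via [build_world()].
#'
#' @param planet A `planet` (see [make_planet()]), or any list with
#'   `climate` and `ice_cells`.
#' @param dir Output directory (created if missing).
#' @param grid The `hex_grid` the table lives on.
#' @param mu Energy-supply scaling for the assembled world.
#' @return `write_world_csv()` the directory, invisibly;
#'   `read_world_csv()` a `world`.
#' @export
write_world_csv <- function(planet, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(planet$climate, file.path(dir, "climate.csv"),
            row.names = FALSE)
  write.csv(data.frame(cell_id = planet$ice_cells),
            file.path(dir, "ice.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_world_csv
#' @export
read_world_csv <- function(dir, grid, mu = 65) {
  cpath <- file.path(dir, "climate.csv")
  if (!file.exists(cpath)) abort(paste0("missing climate table: ", cpath))
  climate <- as_tibble(read.csv(cpath))
  need <- c("cell_id", "month", "temp_c", "precip_mm", "npp")
  miss <- setdiff(need, names(climate))
  if (length(miss))
    abort(paste0("climate table lacks column(s): ",
                 paste(miss, collapse = ", ")))
  months <- sort(unique(climate$month))
  if (!identical(months, 1:12))
    abort(paste0("climate table must hold months 1-12; missing: ",
                 paste(setdiff(1:12, months), collapse = ", ")))
  if (any(abs(climate$temp_c) > 90))
    warn("temperatures outside [-90, 90] C; check units.")
  if (any(climate$npp < 0))
    warn("negative NPP values present; they are clamped to 0 in the energy supply.")
  ipath <- file.path(dir, "ice.csv")
  ice <- if (file.exists(ipath)) read.csv(ipath)$cell_id else integer()
  build_world(grid, climate, ice, mu)
}

#' Write per-hexagon output tables of a run
#'
#' `write_assemblage_csv()` writes the species table and the per-cell
#' richness; `read_patterns_csv()` reads an empirical pattern table
#' (`cell_id` plus the three richness columns) for calibration scoring.
#'
#' @param assemblage An `assemblage`.
#' @param dir Output directory.
#' @param path CSV of `cell_id`, `breeding_migrants`,
#'   `nonbreeding_migrants`, `residents`.
#' @return The directory / a `pattern_set` tibble.
#' @export
write_assemblage_csv <- function(assemblage, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(assemblage$species, file.path(dir, "species.csv"),
            row.names = FALSE)
  write.csv(assemblage$richness, file.path(dir, "richness.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' @rdname write_assemblage_csv
#' @export
read_patterns_csv <- function(path) {
  d <- as_tibble(read.csv(path))
  need <- c("cell_id", "breeding_migrants", "nonbreeding_migrants",
            "residents")
  miss <- setdiff(need, names(d))
  if (length(miss))
    abort(paste0("pattern table lacks column(s): ",
                 paste(miss, collapse = ", ")))
  class(d) <- c("pattern_set", class(d))
  d
}

#' Export grid cells as GeoJSON polygons
#'
#' Cell polygons are built from the geodesic triangulation: the corners of
#' a cell are the centroids of its incident triangles, ordered around the
#' cell centre. Optional per-cell values join as feature properties.
#'
#' @param grid A `hex_grid` built by [hex_grid_freq()] (a grid re-read
#'   from CSV lacks the triangulation).
#' @param path Output file.
#' @param values Optional data frame keyed by `cell_id` whose remaining
#'   columns become feature properties.
#' @return `path`, invisibly.
#' @export
grid_to_geojson <- function(grid, path, values = NULL) {
  tri <- attr(grid, "triangles")
  xyz <- grid_xyz(grid)
  if (is.null(tri)) abort("grid lacks triangulation; rebuild with hex_grid_freq().")
  tc <- (xyz[tri[, 1], ] + xyz[tri[, 2], ] + xyz[tri[, 3], ]) / 3
  tc <- tc / sqrt(rowSums(tc^2))
  incid <- split(rep(seq_len(nrow(tri)), 3), c(tri))
  if (!is.null(values)) values <- as.data.frame(values)
  feats <- lapply(grid$cell_id, function(i) {
    corners <- tc[incid[[as.character(i)]], , drop = FALSE]
    c0 <- xyz[i, ]
    # order corners by angle in the tangent plane at the cell centre
    e1 <- corners[1, ] - sum(corners[1, ] * c0) * c0
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(c0[2] * e1[3] - c0[3] * e1[2],
            c0[3] * e1[1] - c0[1] * e1[3],
            c0[1] * e1[2] - c0[2] * e1[1])
    ang <- atan2(corners %*% e2, corners %*% e1)
    corners <- corners[order(ang), , drop = FALSE]
    lon <- atan2(corners[, 2], corners[, 1]) * 180 / pi
    lat <- asin(clamp01(corners[, 3])) * 180 / pi
    ring <- cbind(lon, lat)
    ring <- rbind(ring, ring[1, ])
    props <- list(cell_id = i, hemisphere = grid$hemisphere[i],
                  area_km2 = grid$area_km2[i])
    if (!is.null(values)) {
      row <- values[values$cell_id == i, , drop = FALSE]
      if (nrow(row) == 1)
        props <- c(props, as.list(row[setdiff(names(row), "cell_id")]))
    }
    list(type = "Feature",
         properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(ring)))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats), path,
    auto_unbox = TRUE, digits = 6)
  invisible(path)
}

#' Serialise range options to CSV or GeoJSON
#'
#' CSV: one row per (option, cell). GeoJSON: one point feature per option
#' centroid (polygons of member cells are available via
#' [grid_to_geojson()] on a per-cell membership table).
#'
#' @param options A `range_options`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_options_csv <- function(options, path) {
  d <- tibble(
    option_id = rep(options$option_id, lengths(options$cells)),
    hemisphere = rep(options$hemisphere, lengths(options$cells)),
    cell_id = unlist(options$cells))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write a run-metadata record
#'
#' Every simulation-affecting setting (parameters, option-generation
#' settings, seeds, package version) in one YAML record, so any published
#' output is reproducible from the record alone.
#'
#' @param params A [sim_params()].
#' @param seed Master seed of the run.
#' @param path Output YAML file.
#' @param extra Optional named list of additional fields (slice ids,
#'   input paths, ...).
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(params, seed, path, extra = list()) {
  rec <- c(list(
    package = "avisim",
    version = as.character(utils::packageVersion("avisim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = if (is.null(seed)) NA else as.integer(seed),
    params = params[c("beta", "alpha", "mu", "be_u", "x", "stop_rule",
                      "max_species")],
    n_options = as.list(params$n_options),
    range_sizes = as.list(params$range_sizes)), extra)
  yaml::write_yaml(rec, path)
  invisible(path)
}
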