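# Icosahedral geodesic world grid.
#
# Cells are the vertices of a Class I geodesic subdivision of the
# icosahedron at frequency n (10 n^2 + 2 cells, of which exactly 12 are
# pentagonal, i.e. have five neighbours). Cell areas follow the equal-area
# convention of icosahedral discrete global grids: every hexagonal cell has
# the same area and each pentagonal cell has 5/6 of it, so the 10 n^2 + 2
# cells partition the full sphere exactly.

icosa_vertices <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v / sqrt(rowSums(v^2))
}

icosa_faces <- function() {
  rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
}

#' Build the hexagonal world grid at a given geodesic frequency
#'
#' Constructs the equal-area icosahedral grid with `10 * freq^2 + 2` cells.
#' The returned object is a tibble with one row per cell and a `neighbors`
#' list-column holding the adjacency (5 or 6 cell ids per cell; exactly 12
#' cells have 5). Use [hex_grid()] to pick the frequency from a target mean
#' cell area instead.
#'
#' @param freq Integer subdivision frequency (>= 2).
#' @return A `hex_grid` tibble with columns `cell_id`, `lon`, `lat`,
#'   `area_km2`, `hemisphere` and `neighbors`.
#' @export
#' @examples
#' g <- hex_grid_freq(4)
#' nrow(g)                      # 10 * 16 + 2
#' sum(lengths(g$neighbors) == 5)  # the 12 pentagons
hex_grid_freq <- function(freq) {
  n <- as.integer(freq)
  if (is.na(n) || n < 2) abort("`freq` must be an integer >= 2.")
  v <- icosa_vertices()
  f <- icosa_faces()

  ij <- expand.grid(i = 0:n, j = 0:n)
  ij <- ij[ij$i + ij$j <= n, ]
  npts <- nrow(ij)
  pts <- matrix(0, npts * 20, 3)
  for (k in 1:20) {
    A <- v[f[k, 1], ]; B <- v[f[k, 2], ]; C <- v[f[k, 3], ]
    w <- cbind(n - ij$i - ij$j, ij$i, ij$j) / n
    P <- w %*% rbind(A, B, C)
    pts[(k - 1) * npts + seq_len(npts), ] <- P / sqrt(rowSums(P^2))
  }
  key <- paste(round(pts[, 1], 8), round(pts[, 2], 8), round(pts[, 3], 8))
  first <- !duplicated(key)
  id <- match(key, key[first])
  xyz <- pts[first, , drop = FALSE]
  n_cells <- nrow(xyz)
  stopifnot(n_cells == 10 * n^2 + 2)

  # triangles of the subdivision (each lies inside exactly one icosa face)
  loc_idx <- function(i, j) match(paste(i, j), paste(ij$i, ij$j))
  up <- ij[ij$i + ij$j <= n - 1, ]
  t_up <- cbind(loc_idx(up$i, up$j), loc_idx(up$i + 1, up$j),
                loc_idx(up$i, up$j + 1))
  dn <- ij[ij$i + ij$j <= n - 2, ]
  t_dn <- if (nrow(dn))
    cbind(loc_idx(dn$i + 1, dn$j), loc_idx(dn$i + 1, dn$j + 1),
          loc_idx(dn$i, dn$j + 1)) else matrix(integer(), 0, 3)
  t_loc <- rbind(t_up, t_dn)
  tri <- do.call(rbind, lapply(1:20, function(k)
    matrix(id[(k - 1) * npts + t_loc], ncol = 3)))

  edges <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(1, 3)])
  edges <- unique(cbind(pmin(edges[, 1], edges[, 2]),
                        pmax(edges[, 1], edges[, 2])))
  nb <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
  nb <- lapply(nb, function(x) sort(unique(x)))

  lat <- asin(clamp01(xyz[, 3])) * 180 / pi
  lon <- atan2(xyz[, 2], xyz[, 1]) * 180 / pi
  a_hex <- earth_area_km2() / (10 * n^2)
  deg <- unname(lengths(nb))
  grid <- tibble(
    cell_id = seq_len(n_cells),
    lon = lon, lat = lat,
    area_km2 = ifelse(deg == 5, a_hex * 5 / 6, a_hex),
    hemisphere = NA_character_,
    neighbors = unname(nb))
  grid <- structure(grid, class = c("hex_grid", class(tibble())),
                    freq = n, xyz = xyz, triangles = tri)
  assign_hemisphere(grid)
}

#' Build the world grid closest to a target mean cell area
#'
#' Picks the geodesic frequency whose mean cell area (Earth surface divided
#' by cell count) is closest to the target, then builds that grid. The
#' default target reproduces the resolution at which a 131-cell range covers
#' about 3.05 million km2 and a 180-cell range about 4.20 million km2
#' (~153 km spacing between adjacent cell centres).
#'
#' @param mean_area_km2 Target mean cell area, between 10,000 and
#'   100,000 km2.
#' @return A `hex_grid` tibble; see [hex_grid_freq()].
#' @export
#' @examples
#' g <- hex_grid(9e4)
#' mean(g$area_km2)
hex_grid <- function(mean_area_km2 = 23320) {
  if (!is.numeric(mean_area_km2) || length(mean_area_km2) != 1 ||
      !is.finite(mean_area_km2))
    abort("`mean_area_km2` must be a single finite number.")
  freqs <- 2:400
  areas <- earth_area_km2() / (10 * freqs^2 + 2)
  if (mean_area_km2 < 1e4 || mean_area_km2 > 1e5) {
    ok <- areas >= 1e4 & areas <= 1e5
    abort(paste0(
      "`mean_area_km2` must lie in [10,000, 100,000] km2; achievable mean ",
      "cell areas in that band run from ", round(min(areas[ok])), " to ",
      round(max(areas[ok])), " km2 (frequencies ", min(freqs[ok]), "-",
      max(freqs[ok]), ")."))
  }
  hex_grid_freq(freqs[which.min(abs(areas - mean_area_km2))])
}

#' Great-circle distance between points on the Earth
#'
#' Haversine distance on a sphere of radius 6371 km. Inputs recycle.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees.
#' @return Distance(s) in km.
#' @export
#' @examples
#' great_circle_km(0, 0, 90, 0)  # quarter circumference, ~10,008 km
great_circle_km <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

#' Label cells as Western or Eastern Hemisphere
#'
#' The Western Hemisphere (`"WH"`) is everything strictly west of 30 degrees
#' W (centroid longitude in `[-180, -30)`); all other cells, including the
#' -30 boundary itself, are Eastern Hemisphere (`"EH"`). Simulations run
#' independently in the two hemispheres.
#'
#' @param grid A `hex_grid`.
#' @return The grid with its `hemisphere` column filled in.
#' @export
assign_hemisphere <- function(grid) {
  grid$hemisphere <- ifelse(grid$lon >= -180 & grid$lon < -30, "WH", "EH")
  grid
}

grid_xyz <- function(grid) attr(grid, "xyz")

# Mean great-circle distance between adjacent cell centres (km).
#' @export
#' @rdname hex_grid_freq
#' @param grid A `hex_grid`.
internode_km <- function(grid) {
  e <- grid_edges(grid)
  mean(great_circle_km(grid$lon[e[, 1]], grid$lat[e[, 1]],
                       grid$lon[e[, 2]], grid$lat[e[, 2]]))
}

grid_edges <- function(grid) {
  nb <- grid$neighbors
  i <- rep(grid$cell_id, lengths(nb))
  j <- unlist(nb)
  keep <- i < j
  cbind(i[keep], j[keep])
}

#' @exportS3Method base::print
print.hex_grid <- function(x, ...) {
  cat(sprintf(
    "<hex_grid> %d cells (freq %d), mean area %.0f km2, internode %.0f km\n",
    nrow(x), attr(x, "freq"), mean(x$area_km2), internode_km(x)))
  NextMethod()
}

# Area-weighted spherical centroid of a set of cells -> c(lon, lat).
cells_centroid <- function(grid, cells) {
  xyz <- grid_xyz(grid)[cells, , drop = FALSE]
  w <- grid$area_km2[cells]
  p <- colSums(xyz * w)
  p <- p / sqrt(sum(p^2))
  c(lon = atan2(p[2], p[1]) * 180 / pi,
    lat = asin(clamp01(p[3])) * 180 / pi)
}
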