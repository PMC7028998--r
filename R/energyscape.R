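# Energy landscape: seasonal climate summaries, the z-scored climatic
# space, the ice mask and the seasonal energy-supply field derived from net
# primary productivity (NPP).

# Month windows of the model's two seasons.
NS_MONTHS <- 5:8            # northern summer: May-August
NW_MONTHS <- c(11, 12, 1, 2) # northern winter: November-February

#' Seasonal means of monthly per-cell fields
#'
#' Averages monthly values over the model's two fixed seasons: northern
#' summer (`NS`, May-August) and northern winter (`NW`, November, December,
#' January, February). The other four months are not used anywhere in the
#' model.
#'
#' @param data A data frame in long format with columns `cell_id`, `month`
#'   (integer 1-12) and the value columns named in `vars`. All 12 months
#'   must be present for every cell.
#' @param vars Character vector of value columns to average.
#' @return A tibble with `cell_id`, `season` (`"NS"`/`"NW"`) and the
#'   seasonal mean of each variable.
#' @export
#' @examples
#' d <- tidyr::expand_grid(cell_id = 1:2, month = 1:12)
#' d$temp_c <- d$month
#' seasonal_means(d, "temp_c")
seasonal_means <- function(data, vars) {
  if (!all(c("cell_id", "month", vars) %in% names(data)))
    abort("`data` needs columns `cell_id`, `month` and the `vars`.")
  months_ok <- data %>%
    group_by(.data$cell_id) %>%
    summarise(ok = all(1:12 %in% .data$month), .groups = "drop")
  if (!all(months_ok$ok)) {
    missing <- setdiff(1:12, unique(data$month))
    abort(paste0("every cell needs all 12 months; missing month(s): ",
                 paste(if (length(missing)) missing else "(per-cell gaps)",
                       collapse = ", ")))
  }
  data %>%
    mutate(season = dplyr::case_when(
      .data$month %in% NS_MONTHS ~ "NS",
      .data$month %in% NW_MONTHS ~ "NW",
      TRUE ~ NA_character_)) %>%
    filter(!is.na(.data$season)) %>%
    group_by(.data$cell_id, .data$season) %>%
    summarise(dplyr::across(dplyr::all_of(vars), mean), .groups = "drop")
}

#' Habitable flags from an ice mask
#'
#' Cells under an ice sheet are not habitable for any bird, regardless of
#' climate: they are excluded from range seeding and growth and their
#' energy supply is zero.
#'
#' @param grid A `hex_grid`.
#' @param ice_cells Integer cell ids covered by ice (may be empty).
#' @return Logical vector, `TRUE` where habitable, ordered as `grid`.
#' @export
apply_ice_mask <- function(grid, ice_cells = integer()) {
  !(grid$cell_id %in% ice_cells)
}

#' The two-dimensional climatic space
#'
#' Builds the climatic space in which range growth measures distances:
#' mean annual temperature, z-standardised, and mean annual precipitation,
#' log10(P + 1)-transformed then z-standardised. Standardisation constants
#' are computed over habitable cells only (sample standard deviation). A
#' zero-variance dimension degenerates: it is set to 0 with a classed
#' warning, so climatic distances in that dimension vanish but the
#' simulation can still run.
#'
#' @param t_ann Mean annual temperature per cell (degrees C).
#' @param p_ann Annual precipitation per cell (mm).
#' @param habitable Logical vector; constants use these cells only.
#' @return A `climate_space`: tibble with `z_t`, `z_logp`, plus the
#'   standardisation constants as attribute `constants`.
#' @export
build_climate_space <- function(t_ann, p_ann,
                                habitable = rep(TRUE, length(t_ann))) {
  if (sum(habitable) < 2)
    abort("need at least 2 habitable cells to build a climatic space.")
  logp <- log10(p_ann + 1)
  std <- function(x, label) {
    m <- mean(x[habitable]); s <- sd(x[habitable])
    if (!is.finite(s) || s == 0) {
      warn(paste0("climatic dimension `", label,
                  "` has zero variance; distances in it are 0."),
           class = "avisim_degenerate_space")
      list(z = rep(0, length(x)), mean = m, sd = 0)
    } else list(z = (x - m) / s, mean = m, sd = s)
  }
  zt <- std(t_ann, "temperature")
  zp <- std(logp, "log10 precipitation")
  out <- tibble(z_t = zt$z, z_logp = zp$z)
  attr(out, "constants") <- list(t_mean = zt$mean, t_sd = zt$sd,
                                 logp_mean = zp$mean, logp_sd = zp$sd)
  class(out) <- c("climate_space", class(out))
  out
}

#' Euclidean distance in the climatic space
#'
#' @param point,optimum Two-column matrices or length-2 vectors of
#'   `(z_t, z_logp)` coordinates; rows recycle.
#' @return Non-negative distances.
#' @export
#' @examples
#' climatic_distance(c(0, 0), c(3, 4))  # 5
climatic_distance <- function(point, optimum) {
  p <- matrix(unlist(point), ncol = 2)
  o <- matrix(unlist(optimum), ncol = 2)
  sqrt((p[, 1] - o[, 1])^2 + (p[, 2] - o[, 2])^2)
}

#' Seasonal energy supply from NPP
#'
#' The carrying capacity for birds in a cell is proportional to the log of
#' its seasonal NPP: `E_S = mu * log10(NPP + 1)`, per season. Negative NPP
#' is set to zero before the log; non-habitable (ice) cells get zero
#' supply. The energy available `E_A` starts equal to the supply and is
#' depleted as species are added.
#'
#' @param npp_ns,npp_nw Seasonal NPP per cell (gC m-2 month-1, the mean of
#'   the season's monthly values).
#' @param habitable Logical per-cell vector.
#' @param mu Supply scaling (default 65).
#' @return An `energy_field` tibble: `cell_id`, `es_ns`, `es_nw`, `ea_ns`,
#'   `ea_nw`.
#' @export
#' @examples
#' energy_supply(999, 0, TRUE, mu = 65)  # es_ns = 195
energy_supply <- function(npp_ns, npp_nw,
                          habitable = rep(TRUE, length(npp_ns)), mu = 65) {
  if (mu <= 0) abort("`mu` must be positive.")
  if (any(!is.finite(npp_ns)) || any(!is.finite(npp_nw)))
    abort("NPP values must be finite.")
  es <- function(npp) mu * log10(pmax(npp, 0) + 1) * as.numeric(habitable)
  out <- tibble(cell_id = seq_along(npp_ns),
                es_ns = es(npp_ns), es_nw = es(npp_nw))
  out$ea_ns <- out$es_ns
  out$ea_nw <- out$es_nw
  class(out) <- c("energy_field", class(out))
  out
}

#' Assemble a simulation-ready world from a grid and monthly climate
#'
#' Computes the seasonal climate summaries, annual means, climatic space,
#' habitable flags and seasonal energy field that the simulator consumes.
#'
#' @param grid A `hex_grid`.
#' @param climate Long tibble with columns `cell_id`, `month`, `temp_c`,
#'   `precip_mm`, `npp` (one row per cell and month).
#' @param ice_cells Integer ids of ice-covered cells.
#' @param mu Energy-supply scaling, see [energy_supply()].
#' @return A `world` object (list with `grid`, `seasonal`, `space`,
#'   `energy`, `habitable`, `mu`).
#' @export
build_world <- function(grid, climate, ice_cells = integer(), mu = 65) {
  need <- c("cell_id", "month", "temp_c", "precip_mm", "npp")
  if (!all(need %in% names(climate)))
    abort(paste0("`climate` needs columns: ", paste(need, collapse = ", ")))
  climate <- arrange(climate, .data$cell_id, .data$month)
  seas <- seasonal_means(climate, c("temp_c", "precip_mm", "npp")) %>%
    tidyr::pivot_wider(names_from = "season",
                       values_from = c("temp_c", "precip_mm", "npp")) %>%
    rename(t_ns = "temp_c_NS", t_nw = "temp_c_NW",
           p_ns = "precip_mm_NS", p_nw = "precip_mm_NW",
           npp_ns = "npp_NS", npp_nw = "npp_NW")
  ann <- climate %>%
    group_by(.data$cell_id) %>%
    summarise(t_ann = mean(.data$temp_c),
              p_ann = sum(.data$precip_mm), .groups = "drop")
  seas <- left_join(seas, ann, by = "cell_id") %>% arrange(.data$cell_id)
  if (!identical(seas$cell_id, grid$cell_id))
    abort("`climate` does not cover exactly the cells of `grid`.")
  habitable <- apply_ice_mask(grid, ice_cells)
  seas$habitable <- habitable
  space <- build_climate_space(seas$t_ann, seas$p_ann, habitable)
  energy <- energy_supply(seas$npp_ns, seas$npp_nw, habitable, mu)
  structure(list(grid = grid, seasonal = seas, space = space,
                 energy = energy, habitable = habitable, mu = mu),
            class = "world")
}

#' @exportS3Method base::print
print.world <- function(x, ...) {
  cat(sprintf(
    "<world> %d cells (%d habitable), mu = %g, total supply NS %.0f / NW %.0f\n",
    nrow(x$grid), sum(x$habitable), x$mu,
    sum(x$energy$es_ns), sum(x$energy$es_nw)))
  invisible(x)
}

#' Remap a lat/lon raster table onto the hexagonal grid
#'
#' Assigns each raster pixel to the nearest cell centre and averages pixel
#' values per cell, weighting by the pixel's area (proportional to
#' cos(latitude) on a regular lat/lon grid). On smooth fields this
#' conserves area-weighted means to within a couple of percent.
#'
#' @param grid A `hex_grid`.
#' @param raster A data frame with `lon`, `lat` and the value columns in
#'   `vars`, one row per pixel of a regular lat/lon raster.
#' @param vars Character vector of value columns to remap.
#' @return A tibble `cell_id` + one column per variable (NA where a cell
#'   caught no pixel).
#' @export
remap_to_grid <- function(grid, raster, vars) {
  if (!all(c("lon", "lat", vars) %in% names(raster)))
    abort("`raster` needs columns `lon`, `lat` and the `vars`.")
  to_rad <- pi / 180
  px <- cbind(cos(raster$lat * to_rad) * cos(raster$lon * to_rad),
              cos(raster$lat * to_rad) * sin(raster$lon * to_rad),
              sin(raster$lat * to_rad))
  gx <- grid_xyz(grid)
  nearest <- integer(nrow(px))
  step <- 20000L
  for (s in seq(1L, nrow(px), by = step)) {
    idx <- s:min(s + step - 1L, nrow(px))
    nearest[idx] <- max.col(px[idx, , drop = FALSE] %*% t(gx), "first")
  }
  w <- cos(raster$lat * to_rad)
  out <- tibble(cell_id = grid$cell_id)
  for (v in vars) {
    num <- tapply(raster[[v]] * w, nearest, sum)
    den <- tapply(w, nearest, sum)
    col <- rep(NA_real_, nrow(grid))
    col[as.integer(names(num))] <- num / den
    out[[v]] <- col
  }
  out
}
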