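# Synthetic planets: self-contained climate/NPP/ice fixtures with the
# latitudinal and seasonal structure the simulator assumes, so every module
# can run without external climate reconstructions.

#' Specify a synthetic planet
#'
#' A planet is described by smooth latitudinal profiles plus seasonal
#' cycles that are anti-phased between the hemispheres (northern summer
#' peaks in July, southern summer in January). Annual mean temperature
#' falls from `t_equator` at the equator by `pole_drop` towards the poles
#' (quadratically in latitude); the seasonal half-amplitude grows linearly
#' from 0 at the equator to `seasonal_amplitude` at the poles. Annual
#' precipitation has wet tropics, dry subtropics and moderately wet
#' temperate latitudes, with a modest wet season in local summer. Monthly
#' NPP follows a logistic temperature limit and a saturating moisture limit
#' (Miami-model constants) times a freezing gate (see [make_npp()]), on
#' the gC m-2 month-1 scale that the default energy-supply scaling
#' `mu = 65` expects. Cells poleward of
#' `ice_latitude` are ice-covered and uninhabitable. Gaussian noise with
#' the stated standard deviations is added to the monthly fields.
#'
#' @param mean_area_km2 Target mean cell area of the grid.
#' @param t_equator Annual mean temperature at the equator (degrees C).
#' @param pole_drop Equator-to-pole drop in annual mean temperature (C).
#' @param seasonal_amplitude Seasonal half-amplitude at the poles (C).
#' @param delta_t Uniform temperature offset (C), used by glacial scenarios.
#' @param precip_tropics,precip_temperate,precip_base Peak annual
#'   precipitation of the tropical and temperate wet belts and the dry
#'   baseline (mm/yr).
#' @param precip_seasonality Relative amplitude of the precipitation
#'   seasonal cycle (0-1), wet season in local summer.
#' @param npp_A Saturating annual NPP (gC m-2 yr-1).
#' @param npp_a,npp_b Logistic temperature-limitation constants.
#' @param npp_c Moisture-limitation rate constant (per mm/yr).
#' @param ice_latitude Length-2 vector `c(north, south)` of absolute
#'   latitudes poleward of which cells are ice.
#' @param noise_sd_t,noise_sd_p Noise standard deviations for monthly
#'   temperature (C) and precipitation (mm).
#' @param seed Default RNG seed for [make_planet()].
#' @return A `planet_spec` (named list).
#' @export
planet_spec <- function(mean_area_km2 = 23320,
                        t_equator = 27, pole_drop = 60,
                        seasonal_amplitude = 30, delta_t = 0,
                        precip_tropics = 2000, precip_temperate = 800,
                        precip_base = 150, precip_seasonality = 0.4,
                        npp_A = 3000, npp_a = 1.315, npp_b = 0.119,
                        npp_c = 0.000664,
                        ice_latitude = c(north = 72, south = 65),
                        noise_sd_t = 0.5, noise_sd_p = 4,
                        seed = NULL) {
  if (seasonal_amplitude < 0) abort("`seasonal_amplitude` must be >= 0.")
  if (any(ice_latitude <= 0) || any(ice_latitude > 90))
    abort("`ice_latitude` must lie in (0, 90].")
  if (length(ice_latitude) == 1)
    ice_latitude <- c(north = ice_latitude, south = ice_latitude)
  spec <- as.list(environment())
  structure(spec, class = "planet_spec")
}

planet_t_ann <- function(spec, lat) {
  spec$t_equator - spec$pole_drop * (abs(lat) / 90)^2 - spec$delta_t
}

planet_p_ann <- function(spec, lat) {
  spec$precip_tropics * exp(-(lat / 15)^2) +
    spec$precip_temperate * exp(-((abs(lat) - 50) / 18)^2) +
    spec$precip_base
}

#' Monthly NPP from monthly temperature and precipitation
#'
#' Minimum of a logistic temperature limit and a saturating moisture limit
#' (the moisture term sees the annualised rate `12 * precip_mm`), divided
#' by 12 to give a monthly rate, then multiplied by a freezing gate
#' `plogis(temp_c / 2)` so that production effectively ceases in
#' sub-freezing months, as it does in monthly output of process vegetation
#' models. NPP is never negative.
#'
#' @param temp_c Monthly mean temperature (C).
#' @param precip_mm Monthly precipitation (mm).
#' @param spec A `planet_spec` supplying the constants.
#' @return Monthly NPP (gC m-2 month-1).
#' @export
#' @examples
#' make_npp(25, 150)   # warm and wet: productive
#' make_npp(25, 0)     # no rain: 0
#' make_npp(-10, 150)  # frozen: ~0
make_npp <- function(temp_c, precip_mm, spec = planet_spec()) {
  t_lim <- spec$npp_A / (1 + exp(spec$npp_a - spec$npp_b * temp_c))
  p_lim <- spec$npp_A * (1 - exp(-spec$npp_c * 12 * pmax(precip_mm, 0)))
  gate <- stats::plogis(temp_c / 2)
  gate * pmax(pmin(t_lim, p_lim), 0) / 12
}

#' Materialise a synthetic planet
#'
#' Builds (or accepts) the grid and evaluates the spec's monthly
#' temperature, precipitation and NPP fields on it, plus the ice mask.
#'
#' @param spec A [planet_spec()].
#' @param grid Optional pre-built `hex_grid`; built from
#'   `spec$mean_area_km2` when omitted.
#' @param seed RNG seed for the noise (defaults to `spec$seed`).
#' @return A `planet`: list with `grid`, `climate` (long tibble `cell_id`,
#'   `month`, `temp_c`, `precip_mm`, `npp`), `ice_cells`, `spec`.
#' @export
make_planet <- function(spec = planet_spec(), grid = NULL,
                        seed = spec$seed) {
  if (is.null(grid)) grid <- hex_grid(spec$mean_area_km2)
  d <- tidyr::expand_grid(cell_id = grid$cell_id, month = 1:12)
  d$lat <- grid$lat[d$cell_id]
  peak <- ifelse(d$lat >= 0, 7, 1)  # local midsummer month
  phase <- cos(2 * pi * (d$month - peak) / 12)
  amp <- spec$seasonal_amplitude * abs(d$lat) / 90
  d$temp_c <- planet_t_ann(spec, d$lat) + amp * phase
  d$precip_mm <- planet_p_ann(spec, d$lat) / 12 *
    (1 + spec$precip_seasonality * phase)
  with_seed_if(seed, {
    if (spec$noise_sd_t > 0)
      d$temp_c <- d$temp_c + rnorm(nrow(d), 0, spec$noise_sd_t)
    if (spec$noise_sd_p > 0)
      d$precip_mm <- d$precip_mm + rnorm(nrow(d), 0, spec$noise_sd_p)
  })
  d$precip_mm <- pmax(d$precip_mm, 0)
  d$npp <- make_npp(d$temp_c, d$precip_mm, spec)
  ice <- grid$cell_id[grid$lat > spec$ice_latitude[["north"]] |
                        grid$lat < -spec$ice_latitude[["south"]]]
  structure(list(grid = grid,
                 climate = select(d, -"lat"),
                 ice_cells = ice, spec = spec),
            class = "planet")
}

#' Derive a glacial scenario from a planet spec
#'
#' Uniform cooling plus expanded ice sheets; every other knob of the spec
#' is preserved.
#'
#' @param spec A [planet_spec()].
#' @param delta_t Additional uniform cooling (C, >= 0).
#' @param ice_latitude New ice-sheet extent, `c(north, south)` absolute
#'   latitudes.
#' @return A modified `planet_spec`.
#' @export
#' @examples
#' lgm <- glacial_scenario(planet_spec(), delta_t = 6,
#'                         ice_latitude = c(north = 50, south = 60))
glacial_scenario <- function(spec, delta_t = 6,
                             ice_latitude = c(north = 50, south = 60)) {
  if (delta_t < 0) abort("`delta_t` must be >= 0.")
  if (length(ice_latitude) == 1)
    ice_latitude <- c(north = ice_latitude, south = ice_latitude)
  spec$delta_t <- spec$delta_t + delta_t
  spec$ice_latitude <- ice_latitude
  spec
}

#' Build a ready-to-simulate world from a planet spec
#'
#' Convenience wrapper: [make_planet()] then [build_world()].
#'
#' @param spec A [planet_spec()].
#' @param grid Optional pre-built grid (shared across scenarios).
#' @param mu Energy-supply scaling.
#' @param seed RNG seed for the planet noise.
#' @return A `world` object.
#' @export
synthetic_world <- function(spec = planet_spec(), grid = NULL, mu = 65,
                            seed = spec$seed) {
  p <- make_planet(spec, grid, seed)
  build_world(p$grid, p$climate, p$ice_cells, mu)
}

#' Named fixture planet specs
#'
#' Presets used throughout tests and examples: `"default"` (seasonal,
#' present-day ice), `"no-seasonality"` (zero seasonal amplitude and
#' aseasonal rainfall: the two seasons are identical up to noise, which is
#' disabled), `"mirror"` (noise-free, hemispherically symmetric) and
#' `"glacial"` (6 C cooler, northern ice to 50 degrees).
#'
#' @param name Fixture name.
#' @param mean_area_km2 Grid resolution passed through to the spec.
#' @return A `planet_spec`.
#' @export
fixture_spec <- function(name = c("default", "no-seasonality", "mirror",
                                  "glacial"),
                         mean_area_km2 = 23320) {
  name <- match.arg(name)
  base <- planet_spec(mean_area_km2 = mean_area_km2)
  switch(name,
    "default" = base,
    "no-seasonality" = planet_spec(mean_area_km2 = mean_area_km2,
                                   seasonal_amplitude = 0,
                                   precip_seasonality = 0,
                                   noise_sd_t = 0, noise_sd_p = 0),
    "mirror" = planet_spec(mean_area_km2 = mean_area_km2,
                           ice_latitude = c(north = 70, south = 70),
                           noise_sd_t = 0, noise_sd_p = 0),
    "glacial" = glacial_scenario(base))
}
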