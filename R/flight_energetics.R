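# Flight energetics: the per-km migration-cost coefficient alpha derived
# from published allometries for flight power, flight speed and basal
# metabolic rate (BMR).

#' Allometric constants behind the migration-cost coefficient
#'
#' Returns the constants of the three allometries and unit conversions from
#' which the per-km migration cost is derived: mechanical flight power
#' (W vs g), cruising flight speed (m/s vs g), BMR (mlO2/h vs g), the
#' oxygen-to-power conversion (172 mlO2/h per W) and the length of one
#' 6-month season in seconds (182 days).
#'
#' @return A named list of constants.
#' @export
#' @examples
#' allometry_constants()$seconds_per_season  # 182 * 86400
allometry_constants <- function() {
  list(
    flight_power_coef = 0.257,  flight_power_exp = 0.763,
    flight_speed_coef = 6.4773, flight_speed_exp = 0.13,
    bmr_coef = 6.7141,          bmr_exp = 0.6452,
    o2_per_watt = 172,
    seconds_per_season = 182 * 86400,
    bmr_season_coef_printed = 6.15e5)
}

check_mass <- function(mass_g) {
  if (!is.numeric(mass_g) || any(!is.finite(mass_g)) || any(mass_g <= 0))
    abort("`mass_g` must be positive and finite.")
}

#' Flight power, flight speed and seasonal BMR allometries
#'
#' `flight_power_watts()` gives the mechanical power of forward flapping
#' flight (J/s), `flight_speed_ms()` the cruising speed (m/s), and
#' `bmr_season()` the basal metabolic energy used over one 6-month season
#' (J), all as functions of body mass in grams. `bmr_season()` offers the
#' exact unit-conversion chain (BMR in mlO2/h divided by 172 mlO2/h per W,
#' times the seconds in 182 days) and the conventional rounded closed form
#' `6.15e5 * M^0.6452`; the two agree within 1%.
#'
#' @param mass_g Body mass in grams (positive).
#' @param form `"exact"` for the full conversion chain, `"printed"` for the
#'   rounded closed form.
#' @param constants Constants list, see [allometry_constants()].
#' @return Numeric vector.
#' @export
#' @examples
#' flight_power_watts(10)       # ~1.49 W
#' bmr_season(1)                # ~6.14e5 J
#' bmr_season(1, "printed")     # 6.15e5 J
flight_power_watts <- function(mass_g, constants = allometry_constants()) {
  check_mass(mass_g)
  constants$flight_power_coef * mass_g^constants$flight_power_exp
}

#' @rdname flight_power_watts
#' @export
flight_speed_ms <- function(mass_g, constants = allometry_constants()) {
  check_mass(mass_g)
  constants$flight_speed_coef * mass_g^constants$flight_speed_exp
}

#' @rdname flight_power_watts
#' @export
bmr_season <- function(mass_g, form = c("exact", "printed"),
                       constants = allometry_constants()) {
  check_mass(mass_g)
  form <- match.arg(form)
  coef <- switch(form,
    exact = constants$bmr_coef / constants$o2_per_watt *
      constants$seconds_per_season,
    printed = constants$bmr_season_coef_printed)
  coef * mass_g^constants$bmr_exp
}

#' Per-km migration-cost coefficient alpha
#'
#' The energetic cost of travelling one km, expressed as a fraction of the
#' basal energy used over one season: `alpha = 1000 * F_W / (F_S * BMR_S)`,
#' with flight power F_W in J/s, flight speed F_S in m/s (the 1000 converts
#' J per metre to J per km) and seasonal basal energy BMR_S in J. Because
#' the three allometric mass exponents nearly cancel
#' (0.763 - 0.13 - 0.6452 = -0.0122), alpha is almost independent of body
#' mass; evaluated at 1 g with the rounded BMR_S coefficient it is
#' 6.45e-5 per km, the default used throughout the simulator.
#'
#' @param mass_g Body mass in grams; the default 1 g makes the residual
#'   mass term exactly 1.
#' @param bmr_form `"printed"` uses the rounded BMR_S coefficient 6.15e5
#'   (the default, giving 6.45e-5); `"exact"` uses the full conversion
#'   chain (giving 6.46e-5).
#' @param constants Constants list, see [allometry_constants()].
#' @return Cost per km, as a fraction of seasonal basal energy use.
#' @export
#' @examples
#' signif(migration_cost_coefficient(), 3)  # 6.45e-5
migration_cost_coefficient <- function(mass_g = 1,
                                       bmr_form = c("printed", "exact"),
                                       constants = allometry_constants()) {
  bmr_form <- match.arg(bmr_form)
  1000 * flight_power_watts(mass_g, constants) /
    (flight_speed_ms(mass_g, constants) *
       bmr_season(mass_g, bmr_form, constants))
}

#' Annual energetic cost of migration
#'
#' Linear in the one-way great-circle distance between the two seasonal
#' range centroids: `m_C = alpha * d_m`, in units of the seasonal basal
#' energy use. Residents (d_m = 0) pay nothing. At the default alpha a
#' species travelling 1000 km pays ~0.065, i.e. ~6.5% of its yearly basal
#' energy use.
#'
#' @param d_m_km Migration distance in km (non-negative).
#' @param alpha Cost per km; defaults to 6.45e-5.
#' @return Cost in units of seasonal basal energy use.
#' @export
#' @examples
#' migration_cost(1000)  # 0.0645
migration_cost <- function(d_m_km, alpha = 6.45e-5) {
  if (any(!is.finite(d_m_km)) || any(d_m_km < 0))
    abort("`d_m_km` must be non-negative and finite.")
  if (any(alpha < 0)) abort("`alpha` must be non-negative.")
  alpha * d_m_km
}

#' Derivation table for the energetic constants
#'
#' One row per quantity in the chain from the allometries to alpha,
#' evaluated at a given body mass.
#'
#' @param mass_g Body mass in grams.
#' @return A tibble with columns `quantity`, `value`, `units`.
#' @export
energetics_table <- function(mass_g = 1) {
  k <- allometry_constants()
  tibble(
    quantity = c("mass", "flight_power", "flight_speed", "bmr",
                 "seconds_per_season", "bmr_season_exact",
                 "bmr_season_printed", "alpha_exact", "alpha_printed",
                 "cost_1000km"),
    value = c(mass_g,
              flight_power_watts(mass_g),
              flight_speed_ms(mass_g),
              k$bmr_coef * mass_g^k$bmr_exp,
              k$seconds_per_season,
              bmr_season(mass_g, "exact"),
              bmr_season(mass_g, "printed"),
              migration_cost_coefficient(mass_g, "exact"),
              migration_cost_coefficient(mass_g, "printed"),
              migration_cost(1000, migration_cost_coefficient(mass_g))),
    units = c("g", "J/s", "m/s", "mlO2/h", "s", "J", "J",
              "per km", "per km", "fraction of seasonal basal use"))
}
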