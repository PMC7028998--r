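# Calibration and sensitivity scans: re-run the full simulation across a
# grid of one parameter, holding everything else (including the option
# sets and sub-seeds) fixed, and score each run against empirical
# patterns when supplied.

scan_score <- function(assemblage, empirical) {
  g <- glance(assemblage)
  row <- tibble(n_species = g$n_species,
                prop_migrants = g$prop_migrants,
                mean_d_m_km = g$mean_d_m_km,
                r_breeding = NA_real_, r_nonbreeding = NA_real_,
                r_residents = NA_real_, composite = NA_real_)
  if (!is.null(empirical) && g$n_species > 0) {
    pc <- pattern_correlation(diversity_patterns(assemblage), empirical)
    row[names(pc)] <- pc
  }
  row
}

#' Scan the functional-response slope beta
#'
#' Runs one full simulation per beta value on a pristine copy of the
#' world, sharing the same option set and seed across grid points, and
#' scores each run by the composite correlation with empirical patterns
#' (when given). The default grid is 0.003 to 0.035 in steps of 0.001:
#' below it not a single species is viable; above it the first species
#' would assimilate an implausible multiple of its basal needs.
#'
#' @param world A `world`.
#' @param betas Numeric vector of beta values.
#' @param empirical Optional empirical `pattern_set` for scoring.
#' @param params Base [sim_params()] (its `beta` is overridden).
#' @param options Optional shared `range_options`; generated once from
#'   `seed` when omitted.
#' @param seed Master seed shared by every grid point.
#' @return A `scan_result` tibble, one row per beta.
#' @export
beta_scan <- function(world, betas = seq(0.003, 0.035, by = 0.001),
                      empirical = NULL, params = sim_params(),
                      options = NULL, seed = NULL) {
  if (is.null(options))
    options <- generate_option_set(
      world, n = params$n_options, sizes = params$range_sizes,
      x = params$x,
      seed = if (is.null(seed)) NULL else derive_seed(seed, "options"))
  rows <- purrr::map(betas, function(b) {
    p <- params; p$beta <- b
    a <- run_simulation(world, options, p, seed = seed)
    dplyr::bind_cols(tibble(parameter = "beta", value = b),
                     scan_score(a, empirical))
  })
  out <- bind_rows(rows)
  class(out) <- c("scan_result", class(out))
  out
}

#' Sensitivity scan over alpha, mu, range size or the growth exponent
#'
#' As [beta_scan()], but varying one of the other knobs while keeping all
#' else fixed: the migration cost `alpha`, the supply scaling `mu`
#' (energy supply is linear in mu, so the field is rescaled), the range
#' sizes (per-hemisphere pairs; options are regenerated per value with the
#' same seed), or the climatic-constraint exponent `x` (likewise).
#'
#' @param world A `world`.
#' @param parameter One of `"alpha"`, `"mu"`, `"range_size"`, `"x"`.
#' @param values Numeric vector for `alpha`, `mu`, `x`; for
#'   `"range_size"`, a list of named vectors `c(WH = ..., EH = ...)`.
#' @param empirical Optional empirical `pattern_set` for scoring.
#' @param params Base [sim_params()].
#' @param seed Master seed shared by every grid point.
#' @return A `scan_result` tibble, one row per value.
#' @export
sensitivity_scan <- function(world,
                             parameter = c("alpha", "mu", "range_size",
                                           "x"),
                             values, empirical = NULL,
                             params = sim_params(), seed = NULL) {
  parameter <- match.arg(parameter)
  opt_seed <- if (is.null(seed)) NULL else derive_seed(seed, "options")
  shared_options <- if (parameter %in% c("alpha", "mu"))
    generate_option_set(world, n = params$n_options,
                        sizes = params$range_sizes, x = params$x,
                        seed = opt_seed)
  rows <- purrr::map(seq_along(values), function(k) {
    v <- values[[k]]
    p <- params
    w <- world
    options <- shared_options
    if (parameter == "alpha") p$alpha <- v
    if (parameter == "mu") {
      p$mu <- v
      scale <- v / world$mu
      w$energy <- dplyr::mutate(world$energy,
        es_ns = .data$es_ns * scale, es_nw = .data$es_nw * scale,
        ea_ns = .data$ea_ns * scale, ea_nw = .data$ea_nw * scale)
      w$mu <- v
    }
    if (parameter == "range_size") {
      p$range_sizes <- v
      options <- generate_option_set(w, n = p$n_options, sizes = v,
                                     x = p$x, seed = opt_seed)
    }
    if (parameter == "x") {
      p$x <- v
      options <- generate_option_set(w, n = p$n_options,
                                     sizes = p$range_sizes, x = v,
                                     seed = opt_seed)
    }
    a <- run_simulation(w, options, p, seed = seed)
    val <- if (parameter == "range_size") unname(v[["WH"]]) else v
    dplyr::bind_cols(tibble(parameter = parameter, value = val),
                     scan_score(a, empirical))
  })
  out <- bind_rows(rows)
  class(out) <- c("scan_result", class(out))
  out
}

#' @exportS3Method base::print
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result> %s over %d values\n",
              x$parameter[1], nrow(x)))
  NextMethod()
}
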