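# The core assembly loop: enumerate candidate distributions (ordered pairs
# of range options within a hemisphere), select the pair with maximal
# energetic fitness, assign the breeding season, deplete the energy field,
# and repeat until the world saturates.

#' Simulation parameters
#'
#' @param beta Slope of the type-I functional response converting energy
#'   available into energy assimilated (the model's one free parameter;
#'   default 0.012, the best-fit value).
#' @param alpha Migration cost per km (default the allometric 6.45e-5, see
#'   [migration_cost_coefficient()]).
#' @param mu Energy-supply scaling, see [energy_supply()].
#' @param be_u Basal energy use per season (1 arbitrary unit, the model's
#'   energy scale).
#' @param n_options,range_sizes Named per-hemisphere option counts and
#'   sizes, see [generate_option_set()].
#' @param x Climatic-constraint exponent for range growth.
#' @param stop_rule `"eprod_nonpositive"` stops when the best candidate's
#'   year-round production is <= 0 (the default); `"assim_below_beu"`
#'   stops when its year-round assimilation falls below the basal use.
#'   The two differ algebraically: production <= 0 is assimilation <=
#'   2 (BE_U + alpha d_m).
#' @param max_species Hard cap on species per hemisphere (safety guard).
#' @return A `sim_params` list.
#' @export
sim_params <- function(beta = 0.012, alpha = 6.45e-5, mu = 65, be_u = 1,
                       n_options = c(WH = 400, EH = 600),
                       range_sizes = c(WH = 131, EH = 180), x = 30,
                       stop_rule = c("eprod_nonpositive",
                                     "assim_below_beu"),
                       max_species = 50000) {
  if (beta <= 0 || beta >= 1) abort("`beta` must be in (0, 1).")
  if (alpha < 0) abort("`alpha` must be >= 0.")
  if (mu <= 0) abort("`mu` must be > 0.")
  stop_rule <- match.arg(stop_rule)
  structure(as.list(environment()), class = "sim_params")
}

#' Mean energy available over a range option
#'
#' The energy available to a species in a season is the arithmetic mean of
#' the per-cell energy available across its seasonal range.
#'
#' @param cells Integer cell ids of the option.
#' @param field An `energy_field` tibble.
#' @param season `"NS"` or `"NW"`.
#' @return A single mean energy value.
#' @export
seasonal_energy_available <- function(cells, field, season = c("NS", "NW")) {
  season <- match.arg(season)
  col <- if (season == "NS") field$ea_ns else field$ea_nw
  mean(col[cells])
}

#' Year-round energetic fitness of a candidate distribution
#'
#' Production is assimilation minus survival costs, summed over the two
#' seasons: `E_prod = beta (E_A_NS + E_A_NW) - 2 (BE_U + alpha d_m)`.
#' Per-season assimilation `beta E_A` is returned alongside, for season
#' assignment and depletion.
#'
#' @param ea_ns,ea_nw Mean energy available over the candidate's two
#'   seasonal ranges (vectors recycle).
#' @param d_m Great-circle distance between the two range centroids (km).
#' @param params A [sim_params()].
#' @return A tibble with `e_prod`, `e_assim_ns`, `e_assim_nw`.
#' @export
#' @examples
#' candidate_fitness(100, 100, 0, sim_params())  # e_prod = 0.4
candidate_fitness <- function(ea_ns, ea_nw, d_m, params = sim_params()) {
  tibble(
    e_prod = params$beta * (ea_ns + ea_nw) -
      2 * (params$be_u + params$alpha * d_m),
    e_assim_ns = params$beta * ea_ns,
    e_assim_nw = params$beta * ea_nw)
}

#' Assign the breeding season of a selected candidate
#'
#' The breeding season is the season with the larger per-season production
#' `beta E_A - (BE_U + alpha d_m)` (the migration cost is charged to each
#' season). Ties break to the season with larger energy available, then to
#' northern summer.
#'
#' @inheritParams candidate_fitness
#' @return `"NS"` or `"NW"`.
#' @export
assign_breeding <- function(ea_ns, ea_nw, d_m, params = sim_params()) {
  prod_ns <- params$beta * ea_ns - (params$be_u + params$alpha * d_m)
  prod_nw <- params$beta * ea_nw - (params$be_u + params$alpha * d_m)
  ifelse(prod_ns > prod_nw, "NS",
         ifelse(prod_nw > prod_ns, "NW",
                ifelse(ea_nw > ea_ns, "NW", "NS")))
}

#' Deplete the energy field under a newly added species
#'
#' Every cell of the species' northern-summer range loses the fraction
#' beta of its own energy available in that season, and likewise for the
#' northern-winter range; a resident (congruent ranges) depletes both
#' seasons, and a cell lying in both seasonal ranges of a migrant is
#' depleted in both seasons independently. Energy never goes negative.
#'
#' @param field An `energy_field`.
#' @param cells_ns,cells_nw Cell ids of the two seasonal ranges.
#' @param beta Depletion fraction (the functional-response slope).
#' @return The updated `energy_field`.
#' @export
deplete <- function(field, cells_ns, cells_nw, beta) {
  field$ea_ns[cells_ns] <- pmax(field$ea_ns[cells_ns] * (1 - beta), 0)
  field$ea_nw[cells_nw] <- pmax(field$ea_nw[cells_nw] * (1 - beta), 0)
  field
}

# All ordered pairs (NS option, NW option) within one hemisphere,
# as index matrices; identical pairs are residents.
#' Enumerate candidate distributions within one hemisphere
#'
#' Candidates are ordered pairs of same-hemisphere options: the first
#' element is occupied in northern summer, the second in northern winter.
#' Identical pairs are resident candidates. Pairs never span hemispheres.
#'
#' @param option_ids Integer option ids of one hemisphere.
#' @return A tibble with columns `ns` and `nw` (all `length(option_ids)^2`
#'   ordered pairs).
#' @export
#' @examples
#' nrow(enumerate_candidates(1:400))  # 160,000
enumerate_candidates <- function(option_ids) {
  tidyr::expand_grid(ns = option_ids, nw = option_ids)
}

# Precompute, for one hemisphere: membership matrix (options x cells) and
# the pairwise centroid distance matrix.
hemisphere_setup <- function(options, hemi, n_cells) {
  idx <- which(options$hemisphere == hemi)
  opt <- options[idx, ]
  sizes <- lengths(opt$cells)
  m <- Matrix::sparseMatrix(
    i = rep(seq_along(idx), sizes), j = unlist(opt$cells),
    x = rep(1 / sizes, sizes), dims = c(length(idx), n_cells))
  d <- outer(seq_along(idx), seq_along(idx), function(i, j)
    great_circle_km(opt$centroid_lon[i], opt$centroid_lat[i],
                    opt$centroid_lon[j], opt$centroid_lat[j]))
  diag(d) <- 0
  list(ids = opt$option_id, member = m, dist = d, cells = opt$cells)
}

# One hemisphere's greedy assembly. Returns species rows, log rows and the
# updated field. Accumulates plain vectors for speed: a run can take
# thousands of steps.
simulate_hemisphere <- function(hemi, setup, field, params,
                                verbose = FALSE) {
  n_opt <- length(setup$ids)
  cost <- 2 * (params$be_u + params$alpha * setup$dist)
  cap <- params$max_species
  sp_i <- integer(0); sp_j <- integer(0); sp_season <- character(0)
  sp_d <- numeric(0); sp_ans <- numeric(0); sp_anw <- numeric(0)
  sp_prod <- numeric(0)
  log_best <- numeric(0)
  n_sp <- 0L
  while (n_sp < cap) {
    ea_ns <- as.numeric(setup$member %*% field$ea_ns)
    ea_nw <- as.numeric(setup$member %*% field$ea_nw)
    e_prod <- params$beta * outer(ea_ns, ea_nw, "+") - cost
    best <- max(e_prod)
    log_best <- c(log_best, best)
    hits <- which(e_prod == best)
    i <- (hits - 1L) %% n_opt + 1L   # NS option
    j <- (hits - 1L) %/% n_opt + 1L  # NW option
    d <- setup$dist[cbind(i, j)]
    season <- assign_breeding(ea_ns[i], ea_nw[j], d, params)
    breed <- ifelse(season == "NS", i, j)
    nonbr <- ifelse(season == "NS", j, i)
    pickt <- order(breed, nonbr)[1]  # deterministic tie-break
    i <- i[pickt]; j <- j[pickt]; season <- season[pickt]; d <- d[pickt]

    e_assim_year <- params$beta * (ea_ns[i] + ea_nw[j])
    saturated <- switch(params$stop_rule,
      eprod_nonpositive = best <= 0,
      assim_below_beu = e_assim_year < params$be_u)
    if (saturated) break

    n_sp <- n_sp + 1L
    sp_i[n_sp] <- i; sp_j[n_sp] <- j; sp_season[n_sp] <- season
    sp_d[n_sp] <- d
    sp_ans[n_sp] <- params$beta * ea_ns[i]
    sp_anw[n_sp] <- params$beta * ea_nw[j]
    sp_prod[n_sp] <- best
    field <- deplete(field, setup$cells[[i]], setup$cells[[j]],
                     params$beta)
    if (verbose && n_sp %% 100 == 0)
      message(sprintf("%s: %d species, best E_prod %.3f", hemi, n_sp,
                      best))
  }
  species <- tibble(
    hemisphere = rep(hemi, n_sp),
    option_ns = setup$ids[sp_i], option_nw = setup$ids[sp_j],
    breeding_option = setup$ids[ifelse(sp_season == "NS", sp_i, sp_j)],
    nonbreeding_option = setup$ids[ifelse(sp_season == "NS", sp_j, sp_i)],
    breeding_season = sp_season,
    d_m = sp_d, e_assim_ns = sp_ans, e_assim_nw = sp_anw,
    e_prod = sp_prod)
  log <- tibble(hemisphere = rep(hemi, length(log_best)),
                step = seq_along(log_best), best_e_prod = log_best)
  list(species = species, log = log, field = field)
}

#' Run the assembly simulation on a world
#'
#' Starting from an empty world (energy available equal to supply), adds
#' one virtual species per step: the candidate distribution (ordered pair
#' of range options) with maximal year-round production is selected, its
#' breeding season assigned, and the energy field depleted under its two
#' seasonal ranges. The loop stops in each hemisphere when the best
#' candidate no longer meets the stop rule. The two hemispheres are
#' simulated independently and merged.
#'
#' @param world A `world` object.
#' @param options A `range_options` set, or `NULL` to generate one from
#'   `params` (with a sub-seed derived from `seed`).
#' @param params A [sim_params()].
#' @param seed Master RNG seed; the run is fully reproducible from it.
#' @param verbose Emit progress messages.
#' @return An `assemblage`: list with `species` (tibble, one row per
#'   species in addition order), `energy` (final field), `richness`
#'   (per-cell species counts), `options`, `params`, `seed`, `log`.
#' @export
run_simulation <- function(world, options = NULL, params = sim_params(),
                           seed = NULL, verbose = FALSE) {
  if (is.null(options))
    options <- generate_option_set(
      world, n = params$n_options, sizes = params$range_sizes,
      x = params$x,
      seed = if (is.null(seed)) NULL else derive_seed(seed, "options"))
  field <- world$energy
  res <- list()
  for (hemi in intersect(c("WH", "EH"), unique(options$hemisphere))) {
    setup <- hemisphere_setup(options, hemi, nrow(world$grid))
    res[[hemi]] <- simulate_hemisphere(hemi, setup, field, params,
                                       verbose)
    # hemispheres share the field object but ranges never overlap across
    # the hemisphere split, so order does not matter
    field$ea_ns <- res[[hemi]]$field$ea_ns
    field$ea_nw <- res[[hemi]]$field$ea_nw
  }
  species <- bind_rows(lapply(res, `[[`, "species"))
  if (nrow(species)) species$species_id <- seq_len(nrow(species))
  s_h <- rep(0L, nrow(world$grid))
  if (nrow(species)) {
    omap <- setNames(options$cells, options$option_id)
    for (r in seq_len(nrow(species))) {
      covered <- union(omap[[as.character(species$option_ns[r])]],
                       omap[[as.character(species$option_nw[r])]])
      s_h[covered] <- s_h[covered] + 1L
    }
  }
  structure(list(
    species = species,
    energy = field,
    richness = tibble(cell_id = world$grid$cell_id, s_h = s_h),
    options = options, params = params, seed = seed,
    log = bind_rows(lapply(res, `[[`, "log"))),
    class = "assemblage")
}

#' @exportS3Method base::print
print.assemblage <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<assemblage> %d species (%.0f%% migrants, mean migration %.0f km)\n",
    g$n_species, 100 * g$prop_migrants,
    ifelse(is.na(g$mean_d_m_km), 0, g$mean_d_m_km)))
  invisible(x)
}

#' Broom-style accessors for assemblages
#'
#' `tidy()` returns the per-species table; `glance()` a one-row summary.
#'
#' @param x An `assemblage`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.assemblage <- function(x, ...) as_tibble(x$species)

#' @rdname tidy.assemblage
#' @export
glance.assemblage <- function(x, ...) {
  sp <- x$species
  mig <- sp$d_m > 0
  tibble(
    n_species = nrow(sp),
    n_migrants = sum(mig),
    prop_migrants = if (nrow(sp)) mean(mig) else NA_real_,
    mean_d_m_km = if (any(mig)) mean(sp$d_m[mig]) else NA_real_,
    total_ea = sum(x$energy$ea_ns) + sum(x$energy$ea_nw))
}
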