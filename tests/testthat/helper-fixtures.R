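# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

test_grid <- function(freq = 6) {
  cached(paste0("grid", freq), hex_grid_freq(freq))
}

# Worlds on the coarse test grid (9e4 km2 target is out of the simulator's
# band, so grids are built by frequency directly).
test_world <- function(name = "default", freq = 6) {
  cached(paste0("world_", name, "_", freq), {
    spec <- fixture_spec(name)
    suppressWarnings(synthetic_world(spec, test_grid(freq), seed = 11))
  })
}

# Scaled-down run settings used throughout: option counts and range sizes
# shrink with the coarse grid in proportion to the full-resolution setup.
small_params <- function(...) {
  sim_params(n_options = c(WH = 24, EH = 36),
             range_sizes = c(WH = 10, EH = 14), ...)
}

test_run <- function() {
  cached("run_default", run_simulation(test_world(), params = small_params(),
                                       seed = 42))
}

# Breadth-first contiguity check under grid adjacency.
is_contiguous <- function(cells, grid) {
  if (length(cells) <= 1) return(TRUE)
  nb <- grid$neighbors
  seen <- cells[1]
  frontier <- cells[1]
  while (length(frontier)) {
    nxt <- intersect(setdiff(unique(unlist(nb[frontier])), seen), cells)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == length(cells)
}

# Independent exhaustive-scan oracle: best year-round production over all
# ordered same-hemisphere option pairs, written as an explicit double loop
# against the raw per-cell field.
oracle_best_eprod <- function(options, hemi, field, params) {
  opt <- options[options$hemisphere == hemi, ]
  best <- -Inf
  for (i in seq_len(nrow(opt))) {
    for (j in seq_len(nrow(opt))) {
      ea_ns <- mean(field$ea_ns[opt$cells[[i]]])
      ea_nw <- mean(field$ea_nw[opt$cells[[j]]])
      d <- great_circle_km(opt$centroid_lon[i], opt$centroid_lat[i],
                           opt$centroid_lon[j], opt$centroid_lat[j])
      if (i == j) d <- 0
      ep <- params$beta * (ea_ns + ea_nw) -
        2 * (params$be_u + params$alpha * d)
      if (ep > best) best <- ep
    }
  }
  best
}

# Replay an assemblage, asserting at every step that the accepted species'
# production equals the exhaustive-scan maximum over its hemisphere, then
# deplete exactly as recorded. Returns the largest absolute discrepancy.
replay_greedy_check <- function(world, assemblage, params) {
  field <- world$energy
  opts <- assemblage$options
  omap <- setNames(opts$cells, opts$option_id)
  worst <- 0
  sp <- assemblage$species
  for (r in seq_len(nrow(sp))) {
    o <- oracle_best_eprod(opts, sp$hemisphere[r], field, params)
    worst <- max(worst, abs(o - sp$e_prod[r]))
    cells_ns <- omap[[as.character(sp$option_ns[r])]]
    cells_nw <- omap[[as.character(sp$option_nw[r])]]
    field <- deplete(field, cells_ns, cells_nw, params$beta)
  }
  # saturation: nothing viable is left in either hemisphere
  for (hemi in unique(opts$hemisphere)) {
    stopifnot(oracle_best_eprod(opts, hemi, field, params) <= 0)
  }
  worst
}

# Minimal assemblage for metrics tests: hand-specified options and species.
fake_assemblage <- function(species, options, n_cells) {
  structure(list(
    species = species, options = options,
    richness = tibble::tibble(cell_id = seq_len(n_cells),
                              s_h = 0L)), class = "assemblage")
}
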