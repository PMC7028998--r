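# Multi-time-slice runner: independent simulations per paleoclimate slice
# (the model has no memory between slices), assembled into time series of
# richness, migrant proportion and migration distance.

#' Simulate a sequence of time slices
#'
#' Runs one independent simulation per world (fresh option set, sub-seed
#' derived from the master seed and the slice id) and assembles per-slice,
#' per-region migration statistics plus the per-cell diversity patterns.
#' With `relative = TRUE` the proportion-of-migrants and distance series
#' are also expressed relative to the first (present) slice.
#'
#' @param worlds Named list of `world` objects, ordered present first
#'   (names are slice ids, e.g. `"0"`, `"10000"`, `"20000"` years BP).
#' @param params A [sim_params()].
#' @param seed Master seed; slice k uses `derive_seed(seed, slice_id)`.
#' @param relative Add present-relative columns.
#' @return A list: `timeseries` (tibble with one row per slice and
#'   region), `patterns` (named list of `pattern_set`s), `assemblages`
#'   (named list).
#' @export
simulate_timeseries <- function(worlds, params = sim_params(),
                                seed = NULL, relative = TRUE) {
  if (is.null(names(worlds)))
    names(worlds) <- as.character(seq_along(worlds) - 1)
  runs <- purrr::imap(worlds, function(w, id) {
    run_simulation(w, options = NULL, params = params,
                   seed = if (is.null(seed)) NULL
                          else derive_seed(seed, "slice", id))
  })
  ts <- purrr::imap(runs, function(a, id) {
    bind_rows(migration_stats(a, "WH"), migration_stats(a, "EH"),
              migration_stats(a)) %>%
      mutate(slice = id, .before = 1)
  }) %>% bind_rows()
  if (relative) {
    present <- names(worlds)[1]
    ts <- ts %>%
      group_by(.data$region) %>%
      mutate(
        rel_prop_migrants = .data$prop_migrants /
          .data$prop_migrants[.data$slice == present],
        rel_mean_d_m = .data$mean_d_m_km /
          .data$mean_d_m_km[.data$slice == present]) %>%
      ungroup()
  }
  list(timeseries = ts,
       patterns = purrr::map(runs, diversity_patterns),
       assemblages = runs)
}
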