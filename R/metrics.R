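# Diversity patterns, migration statistics and pattern correlations.

#' Per-cell diversity patterns of an assemblage
#'
#' Computes the three per-cell richness maps that summarise the seasonal
#' distribution of the avifauna: richness in breeding migrants (species
#' present in the cell only during their breeding season), richness in
#' non-breeding migrants (present only during the non-breeding season) and
#' richness in residents (present year-round). By default a cell lying in
#' both seasonal ranges of a migrant is present year-round there and so
#' counts in neither migrant map (and, being a migrant, not in the
#' resident map either); set `overlap = "resident"` to count such cells as
#' resident occurrences instead.
#'
#' @param assemblage An `assemblage`.
#' @param overlap `"neither"` (default) or `"resident"`.
#' @return A `pattern_set` tibble: `cell_id`, `breeding_migrants`,
#'   `nonbreeding_migrants`, `residents`.
#' @export
diversity_patterns <- function(assemblage,
                               overlap = c("neither", "resident")) {
  overlap <- match.arg(overlap)
  opts <- assemblage$options
  grid_n <- nrow(assemblage$richness)
  omap <- setNames(opts$cells, opts$option_id)
  breed <- integer(grid_n); nonbr <- integer(grid_n); res <- integer(grid_n)
  sp <- assemblage$species
  for (r in seq_len(nrow(sp))) {
    b <- omap[[as.character(sp$breeding_option[r])]]
    n <- omap[[as.character(sp$nonbreeding_option[r])]]
    if (sp$d_m[r] == 0) {
      res[b] <- res[b] + 1L
    } else {
      only_b <- setdiff(b, n)
      only_n <- setdiff(n, b)
      breed[only_b] <- breed[only_b] + 1L
      nonbr[only_n] <- nonbr[only_n] + 1L
      if (overlap == "resident") {
        both <- intersect(b, n)
        res[both] <- res[both] + 1L
      }
    }
  }
  out <- tibble(
    cell_id = seq_len(grid_n),
    breeding_migrants = breed,
    nonbreeding_migrants = nonbr,
    residents = res)
  class(out) <- c("pattern_set", class(out))
  out
}

#' Seasonal difference in richness due to migration
#'
#' Breeding-migrant richness minus non-breeding-migrant richness, per
#' cell: positive where assemblages are richer during the breeding season.
#'
#' @param patterns A `pattern_set`.
#' @return The tibble with an added `seasonal_difference` column.
#' @export
seasonal_difference <- function(patterns) {
  patterns$seasonal_difference <-
    patterns$breeding_migrants - patterns$nonbreeding_migrants
  patterns
}

#' Migration statistics of an assemblage
#'
#' Proportion of species that are migrants (distinct seasonal ranges,
#' d_m > 0) and the mean migration distance among migrants, optionally per
#' region (the hemisphere of the species' options: `"WH"` the Americas,
#' `"EH"` the Old World).
#'
#' @param assemblage An `assemblage`.
#' @param region `NULL` for global, else `"WH"` or `"EH"`.
#' @return A one-row tibble: `region`, `n_species`, `prop_migrants`,
#'   `mean_d_m_km` (NA when there is no migrant or no species).
#' @export
migration_stats <- function(assemblage, region = NULL) {
  sp <- assemblage$species
  if (!is.null(region)) sp <- sp[sp$hemisphere == region, ]
  mig <- sp$d_m > 0
  tibble(
    region = if (is.null(region)) "global" else region,
    n_species = nrow(sp),
    prop_migrants = if (nrow(sp)) mean(mig) else NA_real_,
    mean_d_m_km = if (any(mig)) mean(sp$d_m[mig]) else NA_real_)
}

#' Correlation between simulated and empirical diversity patterns
#'
#' Pearson correlation over cells, per pattern, plus their sum (the
#' composite calibration score). A pattern with zero variance on either
#' side yields an NA correlation, excluded from the composite with a
#' warning.
#'
#' @param simulated,empirical `pattern_set` tibbles on the same grid
#'   (matched by `cell_id`), with columns `breeding_migrants`,
#'   `nonbreeding_migrants`, `residents`.
#' @return A one-row tibble: `r_breeding`, `r_nonbreeding`, `r_residents`,
#'   `composite`.
#' @export
pattern_correlation <- function(simulated, empirical) {
  stopifnot(nrow(simulated) == nrow(empirical))
  empirical <- empirical[match(simulated$cell_id, empirical$cell_id), ]
  one <- function(col) {
    a <- simulated[[col]]; b <- empirical[[col]]
    if (sd(a) == 0 || sd(b) == 0) {
      warn(paste0("pattern `", col,
                  "` has zero variance; correlation undefined."))
      return(NA_real_)
    }
    cor(a, b)
  }
  r <- unname(vapply(
    c("breeding_migrants", "nonbreeding_migrants", "residents"),
    one, numeric(1)))
  tibble(r_breeding = r[1], r_nonbreeding = r[2], r_residents = r[3],
         composite = sum(r, na.rm = TRUE))
}

#' Contrast a pattern set against a reference (e.g. the present)
#'
#' Element-wise difference of the three richness maps, for difference maps
#' between a past slice and the present.
#'
#' @param patterns,reference `pattern_set` tibbles on the same grid.
#' @return A tibble of per-cell differences.
#' @export
pattern_contrast <- function(patterns, reference) {
  stopifnot(nrow(patterns) == nrow(reference))
  reference <- reference[match(patterns$cell_id, reference$cell_id), ]
  tibble(
    cell_id = patterns$cell_id,
    d_breeding_migrants =
      patterns$breeding_migrants - reference$breeding_migrants,
    d_nonbreeding_migrants =
      patterns$nonbreeding_migrants - reference$nonbreeding_migrants,
    d_residents = patterns$residents - reference$residents)
}
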