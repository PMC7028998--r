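# Range options: fixed-size, contiguous, climate-constrained candidate
# ranges grown by a spreading-dye process, per hemisphere.

#' Seeding probabilities for range growth
#'
#' Each range option starts from a single seed cell drawn with probability
#' proportional to `1 / (1 + S_h)`, where `S_h` is the number of species
#' already occupying cell h. Seeding thus avoids piling new options onto
#' already-rich cells. Non-eligible cells (ice, wrong hemisphere) get
#' probability zero.
#'
#' @param s_h Non-negative integer richness per cell.
#' @param eligible Logical per-cell vector (habitable and in the target
#'   hemisphere).
#' @return Probability vector summing to 1 over eligible cells.
#' @export
#' @examples
#' seed_probabilities(c(0, 1), c(TRUE, TRUE))  # 2/3, 1/3
seed_probabilities <- function(s_h, eligible = rep(TRUE, length(s_h))) {
  if (any(s_h < 0)) abort("`s_h` must be non-negative.")
  if (!any(eligible))
    abort("no habitable cell to seed from.", class = "avisim_cannot_seed")
  w <- ifelse(eligible, 1 / (1 + s_h), 0)
  w / sum(w)
}

#' Frontier selection weights for range growth
#'
#' An unoccupied neighbour at climatic distance d from the current optimum
#' gets unnormalised weight `2 * (d + 1)^-x`; a frontier cell adjacent to
#' several occupied cells accumulates the weight once per occupied
#' neighbour. Weights are normalised over the frontier. The default
#' exponent x = 30 makes growth hug the climatic optimum tightly.
#'
#' @param d Non-negative climatic distances of the frontier cells.
#' @param x Decay exponent (> 0).
#' @param multiplicity Number of occupied neighbours of each frontier cell.
#' @return Normalised selection probabilities.
#' @export
#' @examples
#' frontier_weights(c(0, 1), x = 30)
frontier_weights <- function(d, x = 30, multiplicity = 1) {
  if (length(d) == 0)
    abort("empty frontier.", class = "avisim_stalled_growth")
  if (any(d < 0)) abort("`d` must be non-negative.")
  if (x <= 0) abort("`x` must be positive.")
  w <- multiplicity * 2 * (d + 1)^(-x)
  w / sum(w)
}

stalled <- function(hemisphere, got, size) {
  abort(sprintf(
    "range growth stalled in %s at %d of %d cells (frontier empty).",
    hemisphere, got, size), class = "avisim_stalled_growth")
}

#' Grow one contiguous range option by climate-constrained spreading
#'
#' From a seed cell, the range spreads into adjacent unoccupied habitable
#' cells of the same hemisphere until it reaches `size` cells. The climatic
#' optimum starts at the seed's position in the climatic space; first two
#' neighbours of the seed are selected (without replacement, weighted by
#' [frontier_weights()]), then repeatedly 25% (rounded up) of the current
#' frontier is selected, the optimum being redefined each step as the mean
#' climate of the occupied cells. The final batch is truncated to hit
#' `size` exactly, dropping its lowest-weight cells first.
#'
#' @param world A `world` object.
#' @param seed_cell Habitable cell id to start from.
#' @param size Target number of cells (>= 1).
#' @param x Climatic-constraint exponent, see [frontier_weights()].
#' @return A list: `cells` (integer vector, first element the seed),
#'   `seed_cell`, `hemisphere`, `optimum` (final `c(z_t, z_logp)`).
#'   Signals a classed `avisim_stalled_growth` error if the frontier
#'   empties before `size` is reached.
#' @export
grow_range <- function(world, seed_cell, size, x = 30) {
  grid <- world$grid
  if (size < 1) abort("`size` must be >= 1.")
  if (!world$habitable[seed_cell]) abort("`seed_cell` is not habitable.")
  hemi <- grid$hemisphere[seed_cell]
  eligible <- world$habitable & grid$hemisphere == hemi
  nb <- grid$neighbors
  zt <- world$space$z_t
  zp <- world$space$z_logp

  occupied <- rep(FALSE, nrow(grid))
  occupied[seed_cell] <- TRUE
  cells <- seed_cell
  opt <- c(zt[seed_cell], zp[seed_cell])

  pick <- function(cand, k, opt) {
    mult <- vapply(cand, function(c) sum(occupied[nb[[c]]]), integer(1))
    d <- sqrt((zt[cand] - opt[1])^2 + (zp[cand] - opt[2])^2)
    w <- frontier_weights(d, x, mult)
    sel <- if (length(cand) == 1) cand else sample(cand, k, prob = w)
    list(cells = sel, w = w[match(sel, cand)])
  }

  # step 1: two neighbours of the seed
  if (size > 1) {
    cand <- nb[[seed_cell]]
    cand <- cand[eligible[cand] & !occupied[cand]]
    if (length(cand) == 0) stalled(hemi, length(cells), size)
    k <- min(2, length(cand), size - 1)
    sel <- pick(cand, k, opt)$cells
    occupied[sel] <- TRUE
    cells <- c(cells, sel)
  }

  while (length(cells) < size) {
    frontier <- unique(unlist(nb[cells]))
    frontier <- frontier[eligible[frontier] & !occupied[frontier]]
    if (length(frontier) == 0) stalled(hemi, length(cells), size)
    opt <- c(mean(zt[cells]), mean(zp[cells]))
    k <- min(ceiling(0.25 * length(frontier)), length(frontier))
    sel <- pick(frontier, k, opt)
    take <- size - length(cells)
    if (length(sel$cells) > take) {
      keep <- order(sel$w, decreasing = TRUE)[seq_len(take)]
      sel$cells <- sel$cells[keep]
    }
    occupied[sel$cells] <- TRUE
    cells <- c(cells, sel$cells)
  }
  list(cells = cells, seed_cell = seed_cell, hemisphere = hemi,
       optimum = c(z_t = opt[1], z_logp = opt[2]))
}

#' Generate the per-hemisphere sets of range options
#'
#' Seeds and grows the full set of candidate range options for one time
#' slice: by default 400 options of 131 cells in the Western Hemisphere
#' and 600 options of 180 cells in the Eastern Hemisphere (hemisphere
#' sizes reflecting their land areas, option sizes the median bird range).
#' Options are grown independently; a stalled growth is re-seeded up to
#' `max_retries` times before erroring.
#'
#' @param world A `world` object.
#' @param n Named integer vector: options per hemisphere.
#' @param sizes Named integer vector: cells per option, per hemisphere.
#' @param x Climatic-constraint exponent.
#' @param s_h Per-cell richness used in [seed_probabilities()]; defaults
#'   to zero everywhere (options generated before any species exists).
#' @param seed RNG seed (the option set is a deterministic function of the
#'   world, the parameters and this seed).
#' @param max_retries Re-seeding budget per option.
#' @return A `range_options` tibble: `option_id`, `hemisphere`,
#'   `seed_cell`, `size`, `cells` (list-column), `centroid_lon`,
#'   `centroid_lat`.
#' @export
generate_option_set <- function(world, n = c(WH = 400, EH = 600),
                                sizes = c(WH = 131, EH = 180), x = 30,
                                s_h = NULL, seed = NULL,
                                max_retries = 100) {
  grid <- world$grid
  if (is.null(s_h)) s_h <- rep(0L, nrow(grid))
  rows <- with_seed_if(seed, {
    purrr::map(names(n), function(hemi) {
      eligible <- world$habitable & grid$hemisphere == hemi
      if (!any(eligible))
        abort(sprintf(
          "cannot generate options in %s: 0 habitable cells.", hemi),
          class = "avisim_generation_error")
      probs <- seed_probabilities(s_h, eligible)
      purrr::map(seq_len(n[[hemi]]), function(i) {
        for (try in seq_len(max_retries)) {
          seed_cell <- sample(grid$cell_id, 1, prob = probs)
          res <- tryCatch(
            grow_range(world, seed_cell, sizes[[hemi]], x),
            avisim_stalled_growth = function(e) NULL)
          if (!is.null(res)) return(res)
        }
        abort(sprintf(
          "option generation failed in %s after %d retries (%d habitable cells).",
          hemi, max_retries, sum(eligible)),
          class = "avisim_generation_error")
      })
    })
  })
  rows <- purrr::flatten(rows)
  cent <- t(vapply(rows, function(r) cells_centroid(grid, r$cells),
                   numeric(2)))
  out <- tibble(
    option_id = seq_along(rows),
    hemisphere = vapply(rows, `[[`, character(1), "hemisphere"),
    seed_cell = vapply(rows, `[[`, integer(1), "seed_cell"),
    size = vapply(rows, function(r) length(r$cells), integer(1)),
    cells = lapply(rows, `[[`, "cells"),
    centroid_lon = cent[, 1], centroid_lat = cent[, 2])
  class(out) <- c("range_options", class(out))
  out
}

#' @exportS3Method base::print
print.range_options <- function(x, ...) {
  cat(sprintf("<range_options> %d options (%s)\n", nrow(x),
              paste(sprintf("%s: %d x %d cells",
                            unique(x$hemisphere),
                            table(x$hemisphere)[unique(x$hemisphere)],
                            vapply(unique(x$hemisphere), function(h)
                              x$size[x$hemisphere == h][1], integer(1))),
                    collapse = ", ")))
  NextMethod()
}
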