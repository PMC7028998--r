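# Mean Earth radius (km) used for all spherical geometry.
EARTH_RADIUS_KM <- 6371

earth_area_km2 <- function() 4 * pi * EARTH_RADIUS_KM^2

#' Derive a reproducible sub-seed from a master seed and labels
#'
#' All stochastic stages of a run (option generation, per-slice simulation,
#' scan points) draw their randomness from named substreams so that enabling
#' or disabling one stage never shifts the randomness of another. The
#' substream seed is a deterministic 31-bit hash of the master seed and the
#' stage labels.
#'
#' @param master Integer master seed.
#' @param ... Character or numeric labels naming the substream.
#' @return A positive integer seed below 2^31.
#' @export
#' @examples
#' derive_seed(1, "options", "WH")
derive_seed <- function(master, ...) {
  h <- as.double(as.integer(master) %% 2147483647L)
  for (tok in as.character(unlist(list(...)))) {
    for (code in utf8ToInt(tok)) h <- (h * 31 + code) %% 2147483647
  }
  as.integer(max(1, h))
}

# Run code under a temporary RNG seed when one is supplied; otherwise use
# the current RNG stream.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

clamp01 <- function(x) pmax(-1, pmin(1, x))
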