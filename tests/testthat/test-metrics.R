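# A tiny hand-built world: 10 cells in a row; options are index sets.
toy_options <- function(cells_list, hemi = "WH") {
  tibble::tibble(
    option_id = seq_along(cells_list),
    hemisphere = hemi,
    seed_cell = vapply(cells_list, `[`, integer(1), 1),
    size = lengths(cells_list),
    cells = cells_list,
    centroid_lon = 0, centroid_lat = 0)
}

toy_species <- function(breed, nonbr, d_m, hemi = "WH") {
  tibble::tibble(
    hemisphere = hemi,
    option_ns = breed, option_nw = nonbr,
    breeding_option = breed, nonbreeding_option = nonbr,
    breeding_season = "NS", d_m = d_m,
    e_assim_ns = 1, e_assim_nw = 1, e_prod = 0.5,
    species_id = seq_along(breed))
}

test_that("diversity patterns split presence by season of use", {
  opts <- toy_options(list(1:4, 3:6, 8:10))
  # one migrant (ranges 1:4 vs 3:6, overlap 3:4), one resident on 8:10
  sp <- toy_species(breed = c(1L, 3L), nonbr = c(2L, 3L),
                    d_m = c(500, 0))
  a <- fake_assemblage(sp, opts, 10)
  pat <- diversity_patterns(a)
  expect_equal(pat$breeding_migrants, c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(pat$nonbreeding_migrants,
               c(0, 0, 0, 0, 1, 1, 0, 0, 0, 0))
  expect_equal(pat$residents, c(0, 0, 0, 0, 0, 0, 0, 1, 1, 1))
  # the overlap cells 3:4 may instead count as resident occurrences
  pat2 <- diversity_patterns(a, overlap = "resident")
  expect_equal(pat2$residents, c(0, 0, 1, 1, 0, 0, 0, 1, 1, 1))
  # counting identities
  expect_equal(sum(pat$residents), sum(lengths(opts$cells[3])))
  expect_equal(sum(pat$breeding_migrants), length(setdiff(1:4, 3:6)))
})

test_that("an all-resident assemblage has empty migrant maps", {
  a <- test_run()
  res_only <- a
  res_only$species <- a$species[a$species$d_m == 0, ]
  pat <- diversity_patterns(res_only)
  expect_true(all(pat$breeding_migrants == 0))
  expect_true(all(pat$nonbreeding_migrants == 0))
  omap <- setNames(a$options$cells, a$options$option_id)
  expect_equal(sum(pat$residents),
               sum(vapply(res_only$species$breeding_option,
                          function(o) length(omap[[as.character(o)]]),
                          integer(1))))
})

test_that("patterns are invariant to species relabelling", {
  a <- test_run()
  shuffled <- a
  shuffled$species <- a$species[rev(seq_len(nrow(a$species))), ]
  expect_equal(diversity_patterns(a), diversity_patterns(shuffled))
})

test_that("the seasonal difference map is breeding minus non-breeding", {
  opts <- toy_options(list(1:2, 4:5))
  sp <- toy_species(breed = 1L, nonbr = 2L, d_m = 300)
  pat <- seasonal_difference(diversity_patterns(fake_assemblage(sp, opts, 6)))
  expect_equal(pat$seasonal_difference, c(1, 1, 0, -1, -1, 0))
  # no migrants: identically zero
  sp0 <- toy_species(breed = 1L, nonbr = 1L, d_m = 0)
  pat0 <- seasonal_difference(diversity_patterns(fake_assemblage(sp0, opts, 6)))
  expect_true(all(pat0$seasonal_difference == 0))
})

test_that("a mirrored pair of migrants gives an antisymmetric difference map", {
  # cells 1:3 "north", 4:6 "south"; two mirrored migrants
  opts <- toy_options(list(1:3, 4:6))
  sp <- toy_species(breed = c(1L, 2L), nonbr = c(2L, 1L), d_m = c(1, 1))
  pat <- seasonal_difference(diversity_patterns(fake_assemblage(sp, opts, 6)))
  expect_equal(pat$seasonal_difference[1:3], -pat$seasonal_difference[4:6])
})

test_that("migration statistics count distinct-range species", {
  opts <- toy_options(list(1:2, 3:4))
  sp <- toy_species(breed = c(rep(1L, 7), 1L, 1L, 2L),
                    nonbr = c(rep(1L, 7), 2L, 2L, 1L),
                    d_m = c(rep(0, 7), 800, 1200, 400))
  a <- fake_assemblage(sp, opts, 4)
  m <- migration_stats(a)
  expect_equal(m$prop_migrants, 0.3)
  expect_equal(m$mean_d_m_km, 800)
  resid <- fake_assemblage(sp[sp$d_m == 0, ], opts, 4)
  m0 <- migration_stats(resid)
  expect_equal(m0$prop_migrants, 0)
  expect_true(is.na(m0$mean_d_m_km))
})

test_that("migration distance equals the geodesic between range centroids", {
  a <- test_run()
  opts <- a$options
  mig <- a$species[a$species$d_m > 0, ]
  expect_gt(nrow(mig), 0)
  r <- mig[1, ]
  i <- match(r$option_ns, opts$option_id)
  j <- match(r$option_nw, opts$option_id)
  expect_equal(r$d_m,
               great_circle_km(opts$centroid_lon[i], opts$centroid_lat[i],
                               opts$centroid_lon[j], opts$centroid_lat[j]),
               tolerance = 1e-9)
})

test_that("pattern correlations match the textbook Pearson formula", {
  sim <- tibble::tibble(cell_id = 1:5,
                        breeding_migrants = c(0, 1, 3, 5, 2),
                        nonbreeding_migrants = c(4, 1, 0, 0, 2),
                        residents = c(2, 2, 3, 1, 0))
  emp <- tibble::tibble(cell_id = 1:5,
                        breeding_migrants = c(1, 1, 2, 6, 1),
                        nonbreeding_migrants = -c(4, 1, 0, 0, 2),
                        residents = c(9, 9, 9, 8, 7))
  pearson <- function(a, b) {
    n <- length(a)
    (sum(a * b) - n * mean(a) * mean(b)) /
      sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
  }
  pc <- pattern_correlation(sim, emp)
  expect_equal(pc$r_breeding,
               pearson(sim$breeding_migrants, emp$breeding_migrants))
  expect_equal(pc$r_nonbreeding, -1)
  expect_equal(pc$composite,
               pc$r_breeding + pc$r_nonbreeding + pc$r_residents)
  # perfect agreement scores 3
  expect_equal(pattern_correlation(sim, sim)$composite, 3)
})

test_that("zero-variance patterns are flagged and excluded", {
  sim <- tibble::tibble(cell_id = 1:4,
                        breeding_migrants = c(0, 0, 0, 0),
                        nonbreeding_migrants = c(1, 2, 3, 4),
                        residents = c(4, 3, 2, 1))
  expect_warning(pc <- pattern_correlation(sim, sim), "zero variance")
  expect_true(is.na(pc$r_breeding))
  expect_equal(pc$composite, 2)
})

test_that("pattern contrasts subtract a reference slice", {
  pat <- tibble::tibble(cell_id = 1:3, breeding_migrants = c(2, 1, 0),
                        nonbreeding_migrants = c(0, 0, 0),
                        residents = c(5, 5, 5))
  ref <- tibble::tibble(cell_id = 1:3, breeding_migrants = c(1, 1, 1),
                        nonbreeding_migrants = c(0, 1, 0),
                        residents = c(5, 4, 5))
  ct <- pattern_contrast(pat, ref)
  expect_equal(ct$d_breeding_migrants, c(1, 0, -1))
  expect_equal(ct$d_residents, c(0, 1, 0))
})
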