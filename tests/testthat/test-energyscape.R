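monthly_tbl <- function(values_by_month, cells = 1) {
  d <- tidyr::expand_grid(cell_id = seq_len(cells), month = 1:12)
  d$x <- values_by_month[d$month]
  d
}

test_that("seasonal means use exactly the May-Aug and Nov-Feb windows", {
  d <- monthly_tbl(rep(7, 12))
  s <- seasonal_means(d, "x")
  expect_equal(sort(s$season), c("NS", "NW"))
  expect_equal(s$x, c(7, 7))

  vals <- rep(0, 12)
  vals[c(11, 12, 1, 2)] <- c(3, 4, 1, 2)  # Nov..Feb hold 3,4,1,2
  d <- monthly_tbl(vals)
  expect_equal(seasonal_means(d, "x")$x[
    seasonal_means(d, "x")$season == "NW"], 2.5)

  # the unused months never leak into either season
  vals2 <- vals
  vals2[c(3, 4, 9, 10)] <- rnorm(4, 0, 100)
  expect_equal(seasonal_means(monthly_tbl(vals2), "x"),
               seasonal_means(d, "x"))
})

test_that("incomplete month coverage is an input error", {
  d <- monthly_tbl(rep(1, 12))
  expect_error(seasonal_means(d[d$month != 6, ], "x"), "12 months")
})

test_that("energy supply is log-scaled NPP with clamping and an ice zero", {
  expect_equal(energy_supply(0, 0, TRUE)$es_ns, 0)
  expect_equal(energy_supply(-5, -5, TRUE)$es_ns, 0)   # clamped before log
  expect_equal(energy_supply(999, 0, TRUE, mu = 65)$es_ns, 195)
  f <- energy_supply(c(10, 10), c(3, 3), habitable = c(TRUE, FALSE))
  expect_equal(f$es_ns[2], 0)
  expect_equal(f$ea_ns, f$es_ns)
  expect_equal(f$ea_nw, f$es_nw)
  expect_error(energy_supply(NaN, 1, TRUE), "finite")
  # monotone in NPP, linear in mu
  npp <- sort(runif(20, 0, 300))
  es <- energy_supply(npp, npp, rep(TRUE, 20), mu = 65)$es_ns
  expect_true(all(diff(es) >= 0))
  expect_equal(energy_supply(npp, npp, rep(TRUE, 20), mu = 130)$es_ns,
               2 * es)
})

test_that("the climatic space is z-scored over habitable cells only", {
  cs <- build_climate_space(c(0, 10), c(10, 100))
  expect_equal(cs$z_t, c(-1, 1) / sqrt(2))
  hab <- c(TRUE, TRUE, TRUE, FALSE)
  cs2 <- build_climate_space(c(0, 5, 10, 99), c(10, 20, 30, 4000), hab)
  expect_equal(mean(cs2$z_t[hab]), 0, tolerance = 1e-12)
  expect_equal(sd(cs2$z_t[hab]), 1, tolerance = 1e-12)
  expect_equal(mean(cs2$z_logp[hab]), 0, tolerance = 1e-12)
  expect_equal(sd(cs2$z_logp[hab]), 1, tolerance = 1e-12)
})

test_that("z-scoring a zero-variance dimension degenerates gracefully", {
  expect_warning(cs <- build_climate_space(c(4, 4, 4), c(1, 10, 100)),
                 class = "avisim_degenerate_space")
  expect_equal(cs$z_t, c(0, 0, 0))
  expect_equal(climatic_distance(cbind(cs$z_t[1], cs$z_logp[1]),
                                 cbind(cs$z_t[1], cs$z_logp[1])), 0)
})

test_that("standardisation is idempotent", {
  t_ann <- rnorm(50, 10, 8)
  p_ann <- exp(rnorm(50, 5, 1))
  cs <- build_climate_space(t_ann, p_ann)
  # feeding the standardised temperature back in changes nothing
  cs2 <- build_climate_space(cs$z_t, p_ann)
  expect_equal(cs2$z_t, cs$z_t, tolerance = 1e-9)
})

test_that("climatic distance is planar Euclidean in z-space", {
  expect_equal(climatic_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(climatic_distance(c(0, 0), c(3, 4)), 5)
  a <- cbind(rnorm(10), rnorm(10)); b <- cbind(rnorm(10), rnorm(10))
  expect_equal(climatic_distance(a, b), climatic_distance(b, a))
})

test_that("the ice mask overrides climate everywhere it applies", {
  g <- test_grid(4)
  expect_true(all(apply_ice_mask(g)))
  expect_false(any(apply_ice_mask(g, g$cell_id)))
  # a half-iced planet never grows a range into the ice
  w <- test_world("glacial")
  opts <- generate_option_set(w, n = c(WH = 10, EH = 10),
                              sizes = c(WH = 8, EH = 8), seed = 3)
  ice <- which(!w$habitable)
  for (cells in opts$cells) expect_length(intersect(cells, ice), 0)
})

test_that("raster remapping conserves the mean of a smooth field", {
  g <- test_grid(6)
  px <- tidyr::expand_grid(lat = seq(-89, 89, by = 2),
                           lon = seq(-179, 179, by = 2))
  px$value <- 10 + 5 * sin(px$lat * pi / 180) + cos(px$lon * pi / 90)
  remapped <- remap_to_grid(g, px, "value")
  expect_true(all(is.finite(remapped$value)))
  w_px <- cos(px$lat * pi / 180)
  mean_px <- sum(px$value * w_px) / sum(w_px)
  mean_hex <- sum(remapped$value * g$area_km2) / sum(g$area_km2)
  expect_equal(mean_hex, mean_px, tolerance = 0.02)
})

test_that("a world assembles with supply equal to availability", {
  w <- test_world()
  expect_true(all(w$energy$ea_ns == w$energy$es_ns))
  expect_true(all(w$energy$es_ns >= 0))
  expect_true(all(w$energy$es_ns[!w$habitable] == 0))
  expect_equal(mean(w$space$z_t[w$habitable]), 0, tolerance = 1e-9)
  expect_equal(sd(w$space$z_logp[w$habitable]), 1, tolerance = 1e-9)
})
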