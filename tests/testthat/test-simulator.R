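test_that("candidate fitness implements the annual energy budget", {
  p <- sim_params(beta = 0.012)
  expect_equal(candidate_fitness(100, 100, 0, p)$e_prod, 0.4)
  f <- candidate_fitness(150, 120, 2000, p)
  expect_equal(f$e_prod, 0.012 * 270 - 2 * (1 + 6.45e-5 * 2000))
  expect_equal(f$e_prod, 0.982, tolerance = 1e-9)
  expect_equal(f$e_assim_ns, 1.8)
  expect_equal(candidate_fitness(0, 0, 0, p)$e_prod, -2)
})

test_that("seasonal energy available is the range mean", {
  field <- energy_supply(c(10, 100, 40), c(0, 0, 0), rep(TRUE, 3))
  field$ea_ns <- c(10, 30, 99)
  expect_equal(seasonal_energy_available(c(1, 2), field, "NS"), 20)
  field$ea_ns <- rep(7, 3)
  expect_equal(seasonal_energy_available(1:3, field, "NS"), 7)
  field$ea_nw <- rep(0, 3)
  expect_equal(seasonal_energy_available(1:3, field, "NW"), 0)
})

test_that("candidate enumeration is ordered pairs within a hemisphere", {
  e <- enumerate_candidates(1:2)
  expect_equal(nrow(e), 4)
  expect_equal(sum(e$ns == e$nw), 2)
  expect_equal(nrow(enumerate_candidates(1:400)), 160000)
})

test_that("breeding goes to the more productive season", {
  p <- sim_params()
  expect_equal(assign_breeding(200, 10, 0, p), "NS")
  expect_equal(assign_breeding(10, 200, 1000, p), "NW")
  expect_equal(assign_breeding(50, 50, 0, p), "NS")  # tie -> NS
})

test_that("depletion removes the assimilated fraction per cell and season", {
  field <- energy_supply(rep(99, 4), rep(99, 4), rep(TRUE, 4))
  field$ea_ns <- c(100, 50, 10, 80)
  field$ea_nw <- c(100, 50, 10, 80)
  d <- deplete(field, cells_ns = 1:2, cells_nw = 2:3, beta = 0.012)
  expect_equal(d$ea_ns, c(98.8, 49.4, 10, 80))
  expect_equal(d$ea_nw, c(100, 49.4, 9.88, 80))
  # a resident covering a cell depletes it in both seasons
  r <- deplete(field, 1, 1, 0.012)
  expect_equal(r$ea_ns[1], 98.8)
  expect_equal(r$ea_nw[1], 98.8)
  expect_lte(sum(r$ea_ns) + sum(r$ea_nw),
             sum(field$ea_ns) + sum(field$ea_nw))
})

test_that("greedy selection equals the exhaustive-scan maximum at every step", {
  w <- test_world("default", freq = 3)  # 92-cell toy world
  for (s in 1:20) {
    opts <- generate_option_set(w, n = c(WH = 4, EH = 6),
                                sizes = c(WH = 4, EH = 5), seed = s)
    p <- small_params()
    a <- run_simulation(w, opts, p, seed = s)
    expect_gt(nrow(a$species), 0)
    expect_equal(replay_greedy_check(w, a, p), 0, tolerance = 1e-9)
  }
})

test_that("simulations are reproducible, bounded and energy-conserving", {
  a <- test_run()
  w <- test_world()
  a2 <- run_simulation(w, params = small_params(), seed = 42)
  expect_identical(tidy(a), tidy(a2))
  expect_true(all(a$energy$ea_ns >= 0 & a$energy$ea_nw >= 0))
  expect_true(all(a$energy$ea_ns <= w$energy$es_ns + 1e-12))
  expect_true(all(a$energy$ea_nw <= w$energy$es_nw + 1e-12))
  expect_lt(glance(a)$total_ea,
            sum(w$energy$es_ns) + sum(w$energy$es_nw))
  # every accepted species was viable when accepted
  expect_true(all(a$species$e_prod > 0))
  # richness bookkeeping matches the species table
  expect_equal(sum(a$richness$s_h > 0) > 0, TRUE)
})

test_that("the best candidate fitness never improves as the world fills", {
  a <- test_run()
  for (h in unique(a$log$hemisphere)) {
    b <- a$log$best_e_prod[a$log$hemisphere == h]
    expect_true(all(diff(b) <= 1e-9))
  }
})

test_that("without seasonality every simulated species is a resident", {
  w <- test_world("no-seasonality")
  a <- run_simulation(w, params = small_params(), seed = 42)
  expect_gt(nrow(a$species), 0)
  expect_true(all(a$species$d_m == 0))
  expect_equal(glance(a)$prop_migrants, 0)
})

test_that("an unproductive response slope yields an empty world", {
  w <- test_world()
  a <- run_simulation(w, params = small_params(beta = 0.001), seed = 42)
  expect_equal(nrow(a$species), 0)
  expect_equal(glance(a)$n_species, 0)
})

test_that("the alternative stop rule saturates no earlier than the default", {
  w <- test_world()
  a_eprod <- test_run()
  a_assim <- run_simulation(
    w, params = small_params(stop_rule = "assim_below_beu"), seed = 42)
  # E_prod <= 0 means E_assim <= 2(BE_U + alpha d) >= BE_U: the
  # assimilation rule admits species the production rule rejects
  expect_gte(nrow(a_assim$species), nrow(a_eprod$species))
})

test_that("species ids record addition order within the merged table", {
  a <- test_run()
  expect_equal(a$species$species_id, seq_len(nrow(a$species)))
  expect_true(all(diff(match(unique(a$species$hemisphere),
                             a$species$hemisphere)) > 0))
})
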