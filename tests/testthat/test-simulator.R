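test_that("survival_step thins binomially with one global annual draw", {
  g <- flat_grid(5)

  empty <- population_state()
  expect_equal(length(survival_step(empty)$state$idx), 0L)

  st <- point_state(g, c(2, 2), 500)
  certain <- survival_step(st, 1, 1)
  expect_equal(total_population(certain$state), 500)
  expect_equal(certain$u, 1)

  # binomial oracle: u forced to 0.7 via degenerate bounds; mean surviving
  # count over seeded runs within 3 SE of N * u
  n <- 10000L
  runs <- 1000L
  set.seed(99)
  big <- point_state(g, c(2, 2), n)
  totals <- vapply(seq_len(runs), function(i)
    total_population(survival_step(big, 0.7, 0.7)$state), numeric(1))
  se <- sqrt(n * 0.7 * 0.3 / runs)
  expect_lt(abs(mean(totals) - 7000), 3 * se)

  expect_error(survival_step(st, 0.9, 0.5), "survival_low")
})

test_that("growth_step follows the logistic target and conserves structure", {
  g <- flat_grid(5)
  st <- point_state(g, c(2, 2), 1000)

  # hand-evaluated target: 1000 + 0.25*1000*(1 - 1000/1e5) = 1247.5 -> 1248
  set.seed(1)
  grown <- growth_step(st, r = 0.25, k = 1e5, v_halfwidth = 0)
  expect_equal(total_population(grown), 1248)

  set.seed(1)
  expect_equal(total_population(growth_step(st, 0, 1e5, 0)), 1000)
  expect_equal(total_population(growth_step(population_state(), 1, 1e5)), 0)
  expect_error(growth_step(st, r = NA, k = 1e5), "`r`")

  # deficit path: negative increments shrink cells proportionally, never
  # below zero
  # target: 1000 - 0.5*1000*(1 - 1000/1e5) = 505
  two <- population_state(c(0, 1), c(900, 100))
  set.seed(2)
  shrunk <- growth_step(two, r = -0.5, k = 1e5, v_halfwidth = 0)
  expect_equal(total_population(shrunk), 505)
  expect_true(all(shrunk$count >= 0))
})

test_that("population totals match the deterministic logistic recursion", {
  # with survival forced to 1 and the noise term disabled, the simulated
  # total must track the rounded logistic recursion within +/-1 every year
  g <- flat_grid(31)
  for (r in c(0.25, 0.5, 1.0, 1.5)) {
    cfg <- scenario_config(origin = c(15, 15), t = 13, n0 = 1000, r = r,
                           k = 1e5, v_rand_halfwidth = 0,
                           survival_low = 1, survival_high = 1,
                           q_mean = 0.5, n_reps = 1, seed = 3)
    rep <- run_replicate(g, cfg, 17)
    n <- 1000
    for (y in 1:13) {
      n <- max(0, sign(n + r * n * (1 - n / 1e5)) *
                 floor(abs(n + r * n * (1 - n / 1e5)) + 0.5))
      expect_lte(abs(rep$population[y + 1] - n), 1)
    }
  }
})

test_that("movement conserves population and splits best vs random", {
  g <- corridor_grid(21)

  # conservation across arbitrary seeded runs
  set.seed(7)
  st <- population_state(
    slfspread:::cell_index(g, rbind(c(5, 10), c(10, 10), c(15, 3))),
    c(1000L, 2000L, 500L))
  for (i in 1:5) {
    st2 <- movement_step(st, g, q_mean = runif(1), q_sd = 0.05)
    expect_equal(total_population(st2), 3500)
    rc <- slfspread:::cell_rc(g, st2$idx)
    expect_true(all(slfspread:::in_bounds(g, rc)))
  }

  # q_mean = 0.99, q_sd = 0: expected share on the strictly-best neighbor is
  # the Bernoulli(0.99) mass plus 1/8 of the random remainder
  m <- matrix(0.1, 5, 5); m[2, 2] <- 0.9
  gg <- suitability_grid(m)
  n <- 10000L
  set.seed(11)
  moved <- movement_step(point_state(gg, c(2, 2), n), gg, 0.99, 0)
  best_idx <- slfspread:::cell_index(gg, matrix(c(1, 1), ncol = 2))
  share <- moved$count[moved$idx == best_idx] / n
  expect_gte(share, 0.95)
  p_exp <- 0.99 + 0.01 / 8
  expect_lt(abs(share - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n))

  # q_mean = 0.01, q_sd = 0 on a flat surface: every neighbor receives
  # about 1/8, within 3 multinomial SE
  gf <- flat_grid(5)
  n2 <- 80000L
  set.seed(12)
  moved2 <- movement_step(point_state(gf, c(2, 2), n2), gf, 0.01, 0)
  expect_equal(length(moved2$idx), 8L)
  # non-best neighbors receive only the 99% random movers, 1/8 each; the
  # best-ranked neighbor (smallest row-major index, hence first) also
  # absorbs the 1% informed movers
  p_rand <- 0.99 / 8
  se <- sqrt(n2 * p_rand * (1 - p_rand))
  expect_true(all(abs(moved2$count[-1] - n2 * p_rand) < 3 * se))
  expect_lt(abs(moved2$count[1] - n2 * (p_rand + 0.01)), 3 * se)

  # no individual remains in its natal cell
  single <- point_state(gf, c(2, 2), 5000)
  set.seed(13)
  out <- movement_step(single, gf, 0.5)
  expect_false(single$idx %in% out$idx)
})

test_that("mean_normalized_density matches its definition", {
  g <- flat_grid(5)
  expect_equal(mean_normalized_density(point_state(g, c(1, 1), 42)), 1.0)
  st <- population_state(c(0, 1, 2), c(10, 5, 5))
  expect_equal(mean_normalized_density(st), 2 / 3, tolerance = 1e-12)
  expect_equal(mean_normalized_density(population_state()), 0)
})

test_that("human_movement_step honors bounds, founders and event caps", {
  g <- corridor_grid(21)

  cfg0 <- test_cfg(g, h_max = 0)
  st <- point_state(g, c(10, 10), 100000)
  res <- human_movement_step(st, g, cfg0)
  expect_equal(nrow(res$events), 0L)
  expect_identical(res$state$count, st$count)

  # single occupied cell => d = 1; property check over seeded invocations
  cfg10 <- test_cfg(g, h_max = 10)
  set.seed(21)
  n_events <- integer(0)
  for (i in 1:1000) {
    res <- human_movement_step(st, g, cfg10)
    ev <- res$events
    n_events <- c(n_events, nrow(ev))
    if (nrow(ev)) {
      expect_true(all(ev$founders >= 1 & ev$founders <= 60))
      expect_true(all(ev$dest_row >= 0 & ev$dest_row < 21 &
                        ev$dest_col >= 0 & ev$dest_col < 21))
      expect_true(all(ev$distance_km <= sqrt(2) * 20 * 4 + 1e-9))
      expect_equal(total_population(res$state),
                   total_population(st) + sum(ev$founders))
    }
  }
  expect_true(all(n_events <= 10))
  expect_true(any(n_events > 0))   # d = 1, so the trigger fires half the time
  expect_true(any(n_events == 0))
})

test_that("run_year composes the annual processes in order", {
  g <- corridor_grid(21)

  # extinction is absorbing when no human movement can reseed
  cfg <- test_cfg(g, h_max = 0)
  dead <- run_year(population_state(year = 0L), g, cfg)
  expect_equal(total_population(dead$state), 0)
  expect_equal(dead$state$year, 1L)

  # with survival 1, r = 0, no noise and no jumps, N is conserved
  cfg2 <- test_cfg(g, r = 0, h_max = 0)
  cfg2$survival_low <- cfg2$survival_high <- 1
  cfg2$v_rand_halfwidth <- 0
  st <- point_state(g, c(10, 10), 1234)
  set.seed(5)
  for (i in 1:4) st <- run_year(st, g, cfg2)$state
  expect_equal(total_population(st), 1234)

  # bit-for-bit reproducibility under an outer seed
  cfg3 <- test_cfg(g, h_max = 5)
  st0 <- point_state(g, c(10, 10), 500)
  set.seed(6); a <- run_year(st0, g, cfg3)
  set.seed(6); b <- run_year(st0, g, cfg3)
  expect_identical(a, b)
})

test_that("run_replicate records cumulative occupancy within natural range", {
  g <- corridor_grid(21)

  # t = 0: just the origin
  cfg0 <- test_cfg(g, t = 0, n0 = 77)
  rep0 <- run_replicate(g, cfg0, 1)
  expect_equal(rep0$population, 77)
  expect_equal(length(rep0$occupied[[1]]), 1L)

  # natural dispersal only: Chebyshev radius t bound, monotone cumulative sets
  cfg <- test_cfg(g, origin = c(10, 10), t = 6, h_max = 0, q_mean = 0.2)
  rep <- run_replicate(g, cfg, 42)
  for (y in 1:6) {
    rc <- slfspread:::cell_rc(g, rep$occupied[[y + 1]])
    cheb <- pmax(abs(rc[, 1] - 10), abs(rc[, 2] - 10))
    expect_lte(max(cheb), y)
    expect_true(all(rep$occupied[[y]] %in% rep$occupied[[y + 1]]))
  }

  # determinism contract
  expect_identical(run_replicate(g, cfg, 42), rep)
  expect_error(run_replicate(g, test_cfg(g, origin = c(30, 2)), 1),
               "out of bounds")
})

test_that("expand_scenarios builds the full factorial design", {
  g <- flat_grid(5)
  base <- test_cfg(g, t = 13, n_reps = 1000)
  sc <- expand_scenarios(c(0.25, 0.5, 1.0, 1.5), c(0.01, 0.99),
                         c(0, 3, 5, 7, 10), base)
  expect_length(sc, 40L)
  expect_equal(length(unique(vapply(sc, `[[`, character(1), "id"))), 40L)
  expect_equal(length(unique(vapply(sc, `[[`, integer(1), "seed"))), 40L)
  # annual simulation count of the published design
  expect_equal(length(sc) * base$n_reps * base$t, 520000)
  expect_length(expand_scenarios(1, 0.99, 0, base), 1L)
  expect_error(expand_scenarios(numeric(0), 0.99, 0, base), "non-empty")
})

test_that("run_scenario derives stable per-replicate seeds", {
  g <- corridor_grid(21)
  cfg1 <- test_cfg(g, origin = c(10, 10), n_reps = 1, seed = 123)
  one <- run_scenario(g, cfg1)
  expect_length(one, 1L)
  expect_identical(one[[1]],
                   run_replicate(g, cfg1, slfspread:::rep_seed_for(cfg1, 1)))

  cfg10 <- test_cfg(g, origin = c(10, 10), n_reps = 10, seed = 99)
  expect_identical(run_scenario(g, cfg10), run_scenario(g, cfg10))
})

test_that("human-mediated movement raises per-replicate county coverage", {
  # random-movement scenarios keep per-cell densities even enough for the
  # density-scaled event count to stay positive, so jumps actually occur
  g <- synth_suitability(synth_landscape_params(n_rows = 80, n_cols = 80,
                                                seed = 5))
  cm <- synth_counties(g, 25, seed = 6)
  count_counties <- function(h) {
    cfg <- scenario_config(origin = c(40, 40), t = 8, r = 1.0, q_mean = 0.01,
                           h_max = h, n_reps = 30, seed = 31)
    reps <- run_scenario(g, cfg)
    mean(vapply(reps, function(rp) {
      rc <- slfspread:::cell_rc(g, rp$occupied[[9]])
      length(unique(cm$labels[cbind(rc[, 1] + 1, rc[, 2] + 1)]))
    }, numeric(1)))
  }
  expect_gt(count_counties(10), count_counties(0))
})
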