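# Small in-code fixtures shared across the suite.

# A flat grid of constant suitability.
flat_grid <- function(n = 5L, value = 0.5, cell_size_km = 4) {
  suitability_grid(matrix(value, n, n), cell_size_km = cell_size_km)
}

# A grid with a single vertical high-suitability corridor through the
# middle column, rising toward the top row so ranked movement has a
# strict gradient to climb.
corridor_grid <- function(n = 21L) {
  m <- matrix(0.01, n, n)
  mid <- (n + 1L) %/% 2L
  m[, mid] <- seq(0.8, 0.3, length.out = n)
  suitability_grid(m)
}

# Single-cell population state on a grid.
point_state <- function(grid, rc, n, year = 0L) {
  population_state(slfspread:::cell_index(grid, matrix(rc, ncol = 2L)),
                   as.integer(n), year = year)
}

# Deterministic scenario skeleton for unit tests.
test_cfg <- function(grid, ...) {
  args <- list(...)
  defaults <- list(origin = c(2L, 2L), t = 3L, n0 = 100L, r = 0.5,
                   h_max = 0L, n_reps = 2L, seed = 1L)
  defaults[names(args)] <- args
  do.call(scenario_config, defaults)
}
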