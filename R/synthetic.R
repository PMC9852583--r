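#' Parameters for a synthetic suitability landscape
#'
#' Describes a surface emulating the structure of a habitat-suitability
#' prediction for the spotted lanternfly: a very low background, narrow
#' high-suitability corridors standing in for road/rail networks colonized
#' by tree-of-heaven, and a few urban "hubs" with radially decaying
#' suitability. Defaults are calibrated to the published surface summary
#' (cell values with mean about 0.032, SD about 0.093, maximum about 0.81).
#' Hub peaks descend from `hub_suitability` so that distinct hubs have
#' distinct attraction strengths, and each hub's radial gradient gives
#' best-choice movement a stable cell to hill-climb to.
#'
#' @param n_rows,n_cols Grid dimensions (default 150 x 150; at least 50x50
#'   for meaningful corridor structure).
#' @param background Background suitability (default 0.004).
#' @param n_corridors Number of straight corridors (default 4).
#' @param corridor_width Corridor width in cells (default 2).
#' @param corridor_suitability Corridor value (default 0.25).
#' @param n_hubs Number of hubs (default 6).
#' @param hub_radius Hub Gaussian radius sigma in cells (default 4).
#' @param hub_suitability Peak value of the strongest hub (default 0.8);
#'   later hubs step down by 0.05 each.
#' @param noise_sd SD of additive Gaussian noise (default 0.005).
#' @param seed Integer seed.
#' @return An object of class `synth_landscape_params`.
#' @export
synth_landscape_params <- function(n_rows = 150L, n_cols = 150L,
                                   background = 0.004,
                                   n_corridors = 4L, corridor_width = 2L,
                                   corridor_suitability = 0.25,
                                   n_hubs = 6L, hub_radius = 4,
                                   hub_suitability = 0.8,
                                   noise_sd = 0.005, seed = 1L) {
  if (n_rows < 50L || n_cols < 50L)
    stop("synthetic landscapes need at least 50 x 50 cells")
  for (v in c(background, corridor_suitability, hub_suitability))
    if (v < 0 || v > 1) stop("suitability levels must lie in [0, 1]")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 background = background, n_corridors = as.integer(n_corridors),
                 corridor_width = as.integer(corridor_width),
                 corridor_suitability = corridor_suitability,
                 n_hubs = as.integer(n_hubs), hub_radius = hub_radius,
                 hub_suitability = hub_suitability, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_landscape_params")
}

#' Generate a synthetic suitability surface
#'
#' Deterministic given `params$seed`: straight corridors through random
#' interior points at random orientations, Gaussian hub bumps centered on
#' corridor cells, truncated Gaussian noise, all clipped into \[0, 1\].
#'
#' @param params A [synth_landscape_params].
#' @return A [suitability_grid].
#' @export
synth_suitability <- function(params) {
  p <- params
  set.seed(p$seed)
  m <- matrix(p$background, p$n_rows, p$n_cols)
  rows <- matrix(rep(seq_len(p$n_rows), p$n_cols), p$n_rows, p$n_cols)
  cols <- matrix(rep(seq_len(p$n_cols), each = p$n_rows), p$n_rows, p$n_cols)
  corridor <- matrix(FALSE, p$n_rows, p$n_cols)
  if (p$n_corridors > 0L) for (i in seq_len(p$n_corridors)) {
    r0 <- stats::runif(1L, 0.2, 0.8) * p$n_rows
    c0 <- stats::runif(1L, 0.2, 0.8) * p$n_cols
    theta <- stats::runif(1L, 0, pi)
    # distance from each cell center to the infinite line through (r0, c0)
    dist <- abs((rows - r0) * cos(theta) - (cols - c0) * sin(theta))
    corridor <- corridor | (dist <= p$corridor_width / 2)
  }
  m[corridor] <- p$corridor_suitability
  if (p$n_hubs > 0L) {
    corr_cells <- which(corridor)
    for (h in seq_len(p$n_hubs)) {
      peak <- max(0, p$hub_suitability - 0.05 * (h - 1L))
      center <- if (length(corr_cells))
        corr_cells[r_int_unif(1L, 1L, length(corr_cells))]
      else r_int_unif(1L, 1L, p$n_rows * p$n_cols)
      hr <- ((center - 1L) %% p$n_rows) + 1L
      hc <- ((center - 1L) %/% p$n_rows) + 1L
      d2 <- (rows - hr)^2 + (cols - hc)^2
      bump <- peak * exp(-d2 / (2 * p$hub_radius^2))
      m <- pmax(m, bump)
    }
  }
  if (p$noise_sd > 0)
    m <- m + abs(stats::rnorm(length(m), 0, p$noise_sd))
  suitability_grid(pmin(pmax(m, 0), 1))
}

#' Voronoi-style synthetic county tessellation
#'
#' Labels every cell with the nearest of `n_counties` random seed cells
#' (Euclidean distance, ties to the earlier row-major seed), producing a
#' contiguous, exhaustive partition of the grid into counties.
#'
#' @param grid A [suitability_grid].
#' @param n_counties Number of counties (at least 2, at most the cell
#'   count).
#' @param seed Integer seed.
#' @return A [county_map] with ids `1..n_counties`.
#' @export
synth_counties <- function(grid, n_counties, seed = 1L) {
  n_cells <- grid$n_rows * grid$n_cols
  if (n_counties < 2L) stop("need at least 2 counties")
  if (n_counties > n_cells) stop("more counties than cells")
  set.seed(as.integer(seed))
  centers <- sort(sample.int(n_cells, n_counties))  # 1-based row-major
  ctr_r <- (centers - 1L) %/% grid$n_cols
  ctr_c <- (centers - 1L) %% grid$n_cols
  cell_r <- rep(0:(grid$n_rows - 1L), each = grid$n_cols)
  cell_c <- rep(0:(grid$n_cols - 1L), times = grid$n_rows)
  d2 <- outer(ctr_r, cell_r, function(a, b) (a - b)^2) +
    outer(ctr_c, cell_c, function(a, b) (a - b)^2)
  lab <- apply(d2, 2L, which.min)  # ties -> earlier (row-major) seed
  county_map(matrix(lab, grid$n_rows, grid$n_cols, byrow = TRUE))
}

#' Ground-truth specification for a synthetic observation record
#'
#' A known true scenario (notably a true number of human-mediated movements
#' `h*`) plus an explicit per-county-year detection probability. The real
#' detection record conflates arrival and detection; `detection_prob = 1`
#' reproduces that implicit assumption, lower values support robustness
#' checks.
#'
#' @param cfg True [scenario_config] used to generate the spread.
#' @param detection_prob Probability a county with the species present is
#'   detected in a given year (retried every subsequent year); in (0, 1\].
#' @param seed Integer seed for the truth replicate and detection draws.
#' @return An object of class `ground_truth_spec`.
#' @export
ground_truth_spec <- function(cfg, detection_prob = 1, seed = 1L) {
  if (detection_prob <= 0 || detection_prob > 1)
    stop("`detection_prob` must be in (0, 1]")
  structure(list(cfg = cfg, detection_prob = detection_prob,
                 seed = as.integer(seed)),
            class = "ground_truth_spec")
}

#' Generate a synthetic observed-spread record
#'
#' Runs one ground-truth replicate under `truth$cfg` and converts it into a
#' county-level first-detection table: a county's first detection year is
#' the first year in which it contains at least one occupied cell *and* an
#' independent Bernoulli(`detection_prob`) draw succeeds; failed detections
#' are retried every subsequent year the county remains occupied.
#'
#' @param grid A [suitability_grid].
#' @param counties A [county_map].
#' @param truth A [ground_truth_spec].
#' @return List with `observed` (an [observed_occurrence]), and `truth_rep`
#'   (the underlying `rep_result`, for diagnostics).
#' @export
synth_observed <- function(grid, counties, truth) {
  rep <- run_replicate(grid, truth$cfg, truth$seed)
  set.seed(truth$seed + 1L)
  horizon <- length(rep$occupied) - 1L
  first <- stats::setNames(rep(NA_real_, length(counties$ids)),
                           counties$ids)
  for (y in 0:horizon) {
    idx <- rep$occupied[[y + 1L]]
    rc <- cbind(idx %/% grid$n_cols, idx %% grid$n_cols)
    occ_ids <- sort(unique(
      counties$labels[cbind(rc[, 1L] + 1L, rc[, 2L] + 1L)]))
    occ_ids <- occ_ids[occ_ids > 0L]
    for (id in occ_ids) {
      key <- as.character(id)
      if (is.na(first[key]) &&
          stats::runif(1L) <= truth$detection_prob)
        first[key] <- y
    }
  }
  detected <- first[!is.na(first)]
  list(observed = observed_occurrence(
         data.frame(county_id = as.integer(names(detected)),
                    first_detection_year = as.numeric(detected))),
       truth_rep = rep)
}
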