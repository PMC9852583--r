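#' Experiment configuration
#'
#' One object describing a full factorial spread experiment: where the
#' landscape, county map and observed record come from (files or synthetic
#' generators), the base scenario, the factor levels to cross, and the
#' occupancy threshold.
#'
#' @param landscape A [suitability_grid], a raster path, or a
#'   [synth_landscape_params].
#' @param counties A [county_map], a county source accepted by
#'   [rasterize_counties], or an integer `n_counties` to tessellate
#'   synthetically.
#' @param observed An [observed_occurrence], a CSV path with columns
#'   `county_id, first_detection_year`, or a [ground_truth_spec] to simulate
#'   one.
#' @param base_cfg Base [scenario_config].
#' @param r_values,q_means,h_values Factor levels to cross (non-empty).
#' @param tau Occupancy threshold in \[0, 1\] (default 0.95).
#' @param years Evaluation years; default `1:base_cfg$t`.
#' @param out_dir Output directory for artifacts and the manifest.
#' @param seed Global experiment seed.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(landscape, counties, observed, base_cfg,
                              r_values, q_means, h_values,
                              tau = 0.95, years = NULL,
                              out_dir = tempfile("slfspread_"), seed = 1L) {
  if (length(r_values) == 0L || length(q_means) == 0L ||
      length(h_values) == 0L)
    stop("factor lists must be non-empty")
  if (tau < 0 || tau > 1) stop("`tau` must be in [0, 1]")
  structure(list(landscape = landscape, counties = counties,
                 observed = observed, base_cfg = base_cfg,
                 r_values = r_values, q_means = q_means, h_values = h_values,
                 tau = tau,
                 years = if (is.null(years)) seq_len(base_cfg$t) else years,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "experiment_config")
}

resolve_landscape <- function(x) {
  if (inherits(x, "suitability_grid")) return(x)
  if (inherits(x, "synth_landscape_params")) return(synth_suitability(x))
  if (is.character(x)) return(load_raster(x))
  stop("cannot resolve landscape source")
}

resolve_counties <- function(x, grid, seed) {
  if (inherits(x, "county_map")) return(x)
  if (is.numeric(x) && length(x) == 1L)
    return(synth_counties(grid, as.integer(x), seed = seed))
  rasterize_counties(x, grid)
}

resolve_observed <- function(x, grid, counties) {
  if (inherits(x, "observed_occurrence")) return(x)
  if (inherits(x, "ground_truth_spec"))
    return(synth_observed(grid, counties, x)$observed)
  if (is.character(x))
    return(observed_occurrence(utils::read.csv(x)))
  stop("cannot resolve observed-occurrence source")
}

config_hash <- function(cfg) {
  # stable content hash of the scenario settings that determine its output
  key <- paste(cfg$id, cfg$t, cfg$n0, cfg$k, cfg$r, cfg$v_rand_halfwidth,
               cfg$survival_low, cfg$survival_high, cfg$q_mean, cfg$q_sd,
               cfg$h_max, cfg$founder_max, cfg$jump_sd_cells,
               cfg$candidate_iter_max, cfg$origin_pool_cap, cfg$n_reps,
               cfg$seed, sep = "|")
  # djb2-style rolling hash; hex-encoded
  h <- 5381
  for (ch in utf8ToInt(key)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Run a full spread experiment
#'
#' Expands the factorial scenario grid, simulates every scenario, stacks
#' replicates into occupancy probabilities, thresholds them, evaluates the
#' predictions against the observed record, and writes tidy metric and
#' summary tables plus a JSON manifest into `cfg$out_dir`. Scenarios whose
#' metric file already exists under the same config hash are skipped, so an
#' interrupted experiment resumes where it stopped.
#'
#' @param cfg An [experiment_config].
#' @param verbose Log per-scenario progress to stderr (default TRUE).
#' @return The manifest, invisibly: a list with per-scenario entries
#'   (id, factor levels, seed, hash, metrics path) and the paths of the
#'   combined metrics and summary CSVs.
#' @export
run_experiment <- function(cfg, verbose = TRUE) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- resolve_landscape(cfg$landscape)
  counties <- resolve_counties(cfg$counties, grid, seed = cfg$seed)
  observed <- resolve_observed(cfg$observed, grid, counties)
  base <- cfg$base_cfg
  base$seed <- cfg$seed
  scenarios <- expand_scenarios(cfg$r_values, cfg$q_means, cfg$h_values, base)
  entries <- list()
  all_metrics <- list()
  for (sc in scenarios) {
    hash <- config_hash(sc)
    mpath <- file.path(cfg$out_dir,
                       sprintf("metrics_%s_%s.csv", sc$id, hash))
    if (file.exists(mpath)) {
      if (verbose) message("skipping completed scenario ", sc$id)
      metrics <- utils::read.csv(mpath)
    } else {
      if (verbose) message("running scenario ", sc$id,
                           " (", sc$n_reps, " reps)")
      reps <- run_scenario(grid, sc)
      preds <- list(list(
        id = sc$id, r = sc$r, q_mean = sc$q_mean, h_max = sc$h_max,
        cells_by_year = stats::setNames(
          lapply(cfg$years,
                 function(y) threshold_cells(
                   occupancy_probability(reps, y, sc$id), cfg$tau)),
          cfg$years)))
      metrics <- evaluate_scenarios(preds, counties, observed, cfg$years)
      utils::write.csv(metrics, mpath, row.names = FALSE)
    }
    all_metrics[[sc$id]] <- metrics
    entries[[sc$id]] <- list(id = sc$id, r = sc$r, q_mean = sc$q_mean,
                             h_max = sc$h_max, seed = sc$seed, hash = hash,
                             metrics = mpath)
  }
  combined <- do.call(rbind, all_metrics)
  rownames(combined) <- NULL
  metrics_path <- file.path(cfg$out_dir, "metrics.csv")
  utils::write.csv(combined, metrics_path, row.names = FALSE)
  summary_paths <- character()
  for (f in c("year", "r", "q_mean", "h_max")) {
    sp <- file.path(cfg$out_dir, sprintf("summary_%s.csv", f))
    utils::write.csv(summarize_metrics(combined, f), sp, row.names = FALSE)
    summary_paths[f] <- sp
  }
  manifest <- list(seed = cfg$seed, tau = cfg$tau, years = cfg$years,
                   scenarios = entries, metrics = metrics_path,
                   summaries = as.list(summary_paths))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Report summary tables (and optional plots) from a manifest
#'
#' Reads the metric table referenced by a manifest and returns the
#' per-factor summaries; with `plot = TRUE` (requires ggplot2) also writes
#' Recall and F1 vs year line plots by human-movement level.
#'
#' @param manifest Manifest list from [run_experiment], or the path of a
#'   `manifest.json`.
#' @param plot Write line plots next to the metrics file (default FALSE).
#' @return Named list of summary data frames (`year`, `r`, `q_mean`,
#'   `h_max`).
#' @export
report <- function(manifest, plot = FALSE) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest)
  if (is.null(manifest$metrics) || !file.exists(manifest$metrics))
    stop("manifest has no readable metrics table")
  metrics <- utils::read.csv(manifest$metrics)
  if (nrow(metrics) == 0L) stop("metrics table is empty")
  out <- lapply(stats::setNames(nm = c("year", "r", "q_mean", "h_max")),
                function(f) summarize_metrics(metrics, f))
  if (plot && requireNamespace("ggplot2", quietly = TRUE)) {
    dir <- dirname(manifest$metrics)
    for (m in c("recall", "f1")) {
      p <- ggplot2::ggplot(
        metrics,
        ggplot2::aes(x = year, y = metrics[[m]],
                     colour = factor(h_max), group = scenario)) +
        ggplot2::geom_line(alpha = 0.6) +
        ggplot2::labs(colour = "h_max", y = m) +
        ggplot2::theme_minimal()
      ggplot2::ggsave(file.path(dir, sprintf("%s_by_year.pdf", m)), p,
                      width = 7, height = 4)
    }
  }
  out
}
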