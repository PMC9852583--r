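#' County label map
#'
#' An integer label grid aligned cell-for-cell with the suitability grid.
#' Label 0 marks cells outside the evaluation extent; every other label is a
#' county (region) id.
#'
#' @param labels Integer matrix of county ids (0 = outside extent).
#' @return An object of class `county_map` with elements `labels` and `ids`
#'   (sorted nonzero ids).
#' @export
county_map <- function(labels) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix")
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  if (any(is.na(labels)) || any(labels < 0L))
    stop("labels must be non-negative integers")
  structure(list(labels = labels, ids = sort(unique(labels[labels > 0L]))),
            class = "county_map")
}

#' @export
print.county_map <- function(x, ...) {
  cat(sprintf("county_map: %d x %d cells, %d counties\n",
              nrow(x$labels), ncol(x$labels), length(x$ids)))
  invisible(x)
}

#' Rasterize county polygons onto a grid
#'
#' Labels each cell with the id of the polygon containing its center
#' (even-odd ray casting); cells outside all polygons get 0. Accepts either
#' a GeoJSON file of (Multi)Polygons carrying an integer `id` property, or an
#' integer label matrix / ASCII label raster, which passes through directly.
#'
#' @param source GeoJSON path, ASCII-grid path of labels, or integer matrix.
#' @param grid A [suitability_grid] supplying dimensions and geo-transform
#'   (`xll`, `yll`, `cell_size_km`; GeoJSON coordinates must be in the same
#'   planar units).
#' @return A [county_map].
#' @export
rasterize_counties <- function(source, grid) {
  if (is.matrix(source)) {
    if (!all(dim(source) == c(grid$n_rows, grid$n_cols)))
      stop("label matrix dimensions do not match the grid")
    return(county_map(source))
  }
  if (!file.exists(source)) stop("cannot read county source: ", source)
  if (grepl("\\.(geo)?json$", source, ignore.case = TRUE)) {
    gj <- jsonlite::read_json(source)
    feats <- gj$features
    if (is.null(feats)) stop("GeoJSON has no features")
    labels <- matrix(0L, grid$n_rows, grid$n_cols)
    # cell-center coordinates in map units; row 0 is the top raster row
    cx <- grid$xll + (seq_len(grid$n_cols) - 0.5) * grid$cell_size_km
    cy <- grid$yll + (grid$n_rows - seq_len(grid$n_rows) + 0.5) *
      grid$cell_size_km
    for (f in feats) {
      id <- f$properties$id
      if (is.null(id)) stop("every GeoJSON feature needs an `id` property")
      geom <- f$geometry
      polys <- switch(geom$type,
                      Polygon = list(geom$coordinates),
                      MultiPolygon = geom$coordinates,
                      stop("unsupported geometry type: ", geom$type))
      for (poly in polys) {
        ring <- poly[[1L]]  # outer ring; holes unsupported
        px <- vapply(ring, function(p) as.numeric(p[[1]]), numeric(1))
        py <- vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
        for (i in seq_len(grid$n_rows)) for (j in seq_len(grid$n_cols)) {
          if (point_in_polygon(cx[j], cy[i], px, py))
            labels[i, j] <- as.integer(id)
        }
      }
    }
    return(county_map(labels))
  }
  g <- read_label_grid(source)
  if (!all(dim(g) == c(grid$n_rows, grid$n_cols)))
    stop("label raster dimensions do not match the grid")
  county_map(g)
}

point_in_polygon <- function(x, y, px, py) {
  n <- length(px)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if (((py[i] > y) != (py[j] > y)) &&
        (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i]))
      inside <- !inside
    j <- i
  }
  inside
}

read_label_grid <- function(path) {
  lines <- readLines(path, n = 6L)
  n_hdr <- 0L
  nr <- nc <- NA_integer_
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2L && grepl("^[A-Za-z_]+$", parts[1])) {
      if (tolower(parts[1]) == "nrows") nr <- as.integer(parts[2])
      if (tolower(parts[1]) == "ncols") nc <- as.integer(parts[2])
      n_hdr <- n_hdr + 1L
    } else break
  }
  if (is.na(nr) || is.na(nc)) stop("not an ASCII label grid: ", path)
  vals <- scan(path, what = integer(), skip = n_hdr, quiet = TRUE)
  matrix(vals, nr, nc, byrow = TRUE)
}

#' Observed county-level occurrence record
#'
#' Maps county ids to the year the species was first detected there.
#' Presence is cumulative: a county detected in year `y` counts as occupied
#' in every later year.
#'
#' @param first_detection Data frame with columns `county_id` and
#'   `first_detection_year`, or a named numeric vector (names = county ids).
#' @return An object of class `observed_occurrence`.
#' @export
observed_occurrence <- function(first_detection) {
  if (is.data.frame(first_detection)) {
    ids <- as.integer(first_detection$county_id)
    yrs <- as.numeric(first_detection$first_detection_year)
  } else {
    ids <- as.integer(names(first_detection))
    yrs <- as.numeric(first_detection)
  }
  if (anyNA(ids) || anyNA(yrs)) stop("invalid observed-occurrence table")
  structure(list(county_id = ids, first_year = yrs),
            class = "observed_occurrence")
}

observed_ids_at <- function(observed, year) {
  observed$county_id[observed$first_year <= year]
}

#' County-level confusion counts
#'
#' A county is *predicted* iff at least one predicted cell lies inside it,
#' and *observed* iff its first detection is at or before `year`. The 2x2
#' table is counted over the counties of the evaluation extent, so
#' `tp + fp + fn + tn` always equals the county count. An alternative
#' cell-level false-positive count (predicted cells falling in counties with
#' no detections) is available via `fp_level = "cell"`; it replaces `fp`
#' only and is not part of the partition identity.
#'
#' @param predicted Integer matrix of predicted cells with columns `row`,
#'   `col` (0-based), as from [threshold_cells].
#' @param counties A [county_map].
#' @param observed An [observed_occurrence].
#' @param year Evaluation year.
#' @param fp_level `"county"` (default) or `"cell"`.
#' @return List of class `confusion_counts` with `tp`, `fp`, `fn`, `tn`,
#'   `n_counties`.
#' @export
confusion_counts <- function(predicted, counties, observed, year,
                             fp_level = c("county", "cell")) {
  fp_level <- match.arg(fp_level)
  labs <- counties$labels
  if (length(predicted)) {
    if (any(predicted[, 1L] < 0L) || any(predicted[, 1L] >= nrow(labs)) ||
        any(predicted[, 2L] < 0L) || any(predicted[, 2L] >= ncol(labs)))
      stop("predicted cells out of bounds")
    cell_labs <- labs[cbind(predicted[, 1L] + 1L, predicted[, 2L] + 1L)]
    pred_ids <- unique(cell_labs[cell_labs > 0L])
  } else {
    cell_labs <- integer(0)
    pred_ids <- integer(0)
  }
  obs_ids <- intersect(observed_ids_at(observed, year), counties$ids)
  tp <- length(intersect(pred_ids, obs_ids))
  fp <- length(setdiff(pred_ids, obs_ids))
  fn <- length(setdiff(obs_ids, pred_ids))
  tn <- length(counties$ids) - tp - fp - fn
  if (fp_level == "cell")
    fp <- sum(cell_labs > 0L & !(cell_labs %in% obs_ids))
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 n_counties = length(counties$ids)),
            class = "confusion_counts")
}

#' Forecast-verification metrics
#'
#' Standard Precision `tp / (tp + fp)`, Recall `tp / (tp + fn)` and
#' `F1 = 2 P R / (P + R)`. Degenerate 0/0 ratios return 0 by convention
#' (this affects only scenarios predicting or observing nothing).
#'
#' @param c A `confusion_counts` object (any list with `tp`, `fp`, `fn`).
#' @return A value in \[0, 1\].
#' @export
precision <- function(c) {
  if (c$tp + c$fp == 0) 0 else c$tp / (c$tp + c$fp)
}

#' @rdname precision
#' @export
recall <- function(c) {
  if (c$tp + c$fn == 0) 0 else c$tp / (c$tp + c$fn)
}

#' @rdname precision
#' @export
f1_score <- function(c) {
  p <- precision(c); r <- recall(c)
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

#' Evaluate scenario predictions against the observed record
#'
#' Computes one metric record per scenario-year from per-year thresholded
#' cell sets.
#'
#' @param predictions List with one entry per scenario; each entry is a list
#'   with fields `id`, `r`, `q_mean`, `h_max`, and `cells_by_year` (a named
#'   list, year -> predicted-cell matrix as from [threshold_cells]).
#' @param counties A [county_map].
#' @param observed An [observed_occurrence].
#' @param years Integer vector of evaluation years.
#' @return Data frame with columns `scenario`, `r`, `q_mean`, `h_max`,
#'   `year`, `tp`, `fp`, `fn`, `tn`, `precision`, `recall`, `f1`.
#' @export
evaluate_scenarios <- function(predictions, counties, observed, years) {
  rows <- list()
  for (p in predictions) {
    for (y in years) {
      cells <- p$cells_by_year[[as.character(y)]]
      if (is.null(cells)) {
        warning(sprintf("scenario %s: no prediction for year %d, skipped",
                        p$id, y))
        next
      }
      cc <- confusion_counts(cells, counties, observed, y)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = p$id, r = p$r, q_mean = p$q_mean, h_max = p$h_max,
        year = y, tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn,
        precision = precision(cc), recall = recall(cc), f1 = f1_score(cc))
    }
  }
  if (length(rows) == 0L)
    return(data.frame(scenario = character(), r = numeric(),
                      q_mean = numeric(), h_max = integer(), year = integer(),
                      tp = integer(), fp = integer(), fn = integer(),
                      tn = integer(), precision = numeric(),
                      recall = numeric(), f1 = numeric()))
  do.call(rbind, rows)
}

#' Summarize metrics by a design factor
#'
#' Mean and standard error (SD / sqrt(n); 0 when n = 1) of Precision,
#' Recall and F1 per level of one design factor, ordered by level — the
#' tidy table that downstream ANOVA / post-hoc analyses consume.
#'
#' @param records Metric data frame from [evaluate_scenarios].
#' @param factor One of `"year"`, `"r"`, `"q_mean"`, `"h_max"`.
#' @return Data frame with columns `factor`, `level`, `n`, and
#'   `<metric>_mean` / `<metric>_se` for each of precision, recall, f1.
#' @export
summarize_metrics <- function(records,
                              factor = c("year", "r", "q_mean", "h_max")) {
  factor <- match.arg(factor)
  if (nrow(records) == 0L) stop("no metric records to summarize")
  levels <- sort(unique(records[[factor]]))
  out <- lapply(levels, function(lv) {
    sub <- records[records[[factor]] == lv, ]
    row <- data.frame(factor = factor, level = lv, n = nrow(sub))
    for (m in c("precision", "recall", "f1")) {
      x <- sub[[m]]
      row[[paste0(m, "_mean")]] <- mean(x)
      row[[paste0(m, "_se")]] <-
        if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
    }
    row
  })
  do.call(rbind, out)
}
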