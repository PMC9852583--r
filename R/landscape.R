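#' Construct a habitat-suitability grid
#'
#' A `suitability_grid` holds a rectangular surface of per-cell establishment
#' suitability values in \[0, 1\] on square cells (4 km by default, matching
#' the resolution at which an adult spotted lanternfly completes its annual
#' egg-to-oviposition movement). The surface drives both the ranked
#' Moore-neighborhood movement of individuals and the selection of
#' human-mediated jump destinations.
#'
#' Grid coordinates throughout the package are 0-based `(row, col)` pairs with
#' row 0 the top raster row, so that cells round-trip unambiguously through
#' raster files.
#'
#' @param values Numeric matrix of suitability values; all finite, in
#'   \[0, 1\]. Must have at least 9 cells so interior cells have a full
#'   Moore neighborhood.
#' @param cell_size_km Side length of a cell in km (default 4).
#' @param xll,yll Coordinates of the lower-left corner of the lower-left
#'   cell (an optional geo-transform carried through for raster
#'   round-tripping).
#' @return An object of class `suitability_grid` with elements `values`,
#'   `n_rows`, `n_cols`, `cell_size_km`, `xll`, `yll`.
#' @examples
#' g <- suitability_grid(matrix(runif(25), 5, 5))
#' g$n_rows
#' @export
suitability_grid <- function(values, cell_size_km = 4, xll = 0, yll = 0) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (length(values) < 9)
    stop("grid must have at least 9 cells")
  if (any(!is.finite(values)))
    stop("all suitability values must be finite")
  if (any(values < 0 | values > 1))
    stop("suitability values must lie in [0, 1]")
  if (cell_size_km <= 0)
    stop("`cell_size_km` must be positive")
  structure(
    list(values = values, n_rows = nrow(values), n_cols = ncol(values),
         cell_size_km = cell_size_km, xll = xll, yll = yll),
    class = "suitability_grid")
}

#' @export
print.suitability_grid <- function(x, ...) {
  cat(sprintf("suitability_grid: %d x %d cells of %g km\n",
              x$n_rows, x$n_cols, x$cell_size_km))
  cat(sprintf("  values: min %.4g, mean %.4g, max %.4g\n",
              min(x$values), mean(x$values), max(x$values)))
  invisible(x)
}

# 0-based (row, col) <-> 0-based linear index (row-major). Linear indices are
# the internal sparse-state key; row-major order is also the documented
# deterministic tie-break order.
cell_index <- function(grid, rc) {
  rc <- matrix(as.integer(rc), ncol = 2)
  rc[, 1L] * grid$n_cols + rc[, 2L]
}

cell_rc <- function(grid, idx) {
  idx <- as.integer(idx)
  cbind(row = idx %/% grid$n_cols, col = idx %% grid$n_cols)
}

cell_suitability <- function(grid, idx) {
  rc <- cell_rc(grid, idx)
  grid$values[cbind(rc[, 1L] + 1L, rc[, 2L] + 1L)]
}

in_bounds <- function(grid, rc) {
  rc[, 1L] >= 0L & rc[, 1L] < grid$n_rows &
    rc[, 2L] >= 0L & rc[, 2L] < grid$n_cols
}

#' Read a suitability raster
#'
#' Reads a single-band raster into a [suitability_grid]. ESRI ASCII grids
#' (`.asc`) are parsed directly; GeoTIFF files are read through the `tiff`
#' package (band values only — plain TIFF tags carry no geo-transform, so
#' `xll`/`yll` default to 0 unless supplied). Values are clipped into
#' \[0, 1\] and no-data cells become suitability 0, so that cells without
#' information can never rank as best movement or jump destinations.
#'
#' @param path File path.
#' @param format `"ascii_grid"` or `"geotiff"`; the default guesses from the
#'   file extension.
#' @param cell_size_km Cell size used when the file does not carry one
#'   (GeoTIFF path); ASCII grids take it from the `CELLSIZE` header.
#' @return A [suitability_grid].
#' @export
load_raster <- function(path, format = c("auto", "ascii_grid", "geotiff"),
                        cell_size_km = 4) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read raster: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("tif", "tiff")) "geotiff" else "ascii_grid"
  }
  if (format == "ascii_grid") {
    read_ascii_grid(path)
  } else {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("GeoTIFF support requires the 'tiff' package")
    v <- tiff::readTIFF(path, as.is = FALSE)
    if (length(dim(v)) == 3L) {
      if (dim(v)[3] != 1L) stop("multi-band raster not supported: ", path)
      v <- v[, , 1L]
    }
    v[!is.finite(v)] <- 0
    v <- pmin(pmax(v, 0), 1)
    suitability_grid(v, cell_size_km = cell_size_km)
  }
}

read_ascii_grid <- function(path) {
  lines <- readLines(path, n = 6L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2L && grepl("^[A-Za-z_]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1L
    } else break
  }
  need <- c("ncols", "nrows")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid (missing NCOLS/NROWS header): ", path)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  vals <- scan(path, what = numeric(), skip = n_hdr, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop(sprintf("ASCII grid body has %d values, expected %d",
                 length(vals), nr * nc))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- 0
  m[!is.finite(m)] <- 0
  m <- pmin(pmax(m, 0), 1)
  cs <- if (!is.null(hdr$cellsize)) hdr$cellsize / 1 else 4
  # CELLSIZE in these files is in map units; the synthetic writers emit km.
  suitability_grid(m, cell_size_km = cs,
                   xll = if (is.null(hdr$xllcorner)) 0 else hdr$xllcorner,
                   yll = if (is.null(hdr$yllcorner)) 0 else hdr$yllcorner)
}

#' Write a grid as an ESRI ASCII raster
#'
#' Works for both [suitability_grid] objects and plain numeric matrices
#' (e.g. occupancy-probability surfaces).
#'
#' @param x A `suitability_grid`, `occupancy_probability`, or numeric matrix.
#' @param path Output path.
#' @param nodata No-data sentinel written in the header.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(x, path, nodata = -9999) {
  if (inherits(x, "suitability_grid")) {
    m <- x$values; cs <- x$cell_size_km; xll <- x$xll; yll <- x$yll
  } else if (inherits(x, "occupancy_probability")) {
    m <- x$values; cs <- 4; xll <- 0; yll <- 0
  } else {
    m <- x; cs <- 4; xll <- 0; yll <- 0
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("NCOLS %d", ncol(m)),
    sprintf("NROWS %d", nrow(m)),
    sprintf("XLLCORNER %.10g", xll),
    sprintf("YLLCORNER %.10g", yll),
    sprintf("CELLSIZE %.10g", cs),
    sprintf("NODATA_VALUE %g", nodata)), con)
  utils::write.table(format(m, trim = TRUE, digits = 10, scientific = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Downsample a suitability grid by block aggregation
#'
#' Aggregates `factor` x `factor` blocks of cells with the given statistic;
#' trailing partial blocks at the right/bottom edges aggregate over the cells
#' they contain.
#'
#' @param grid A [suitability_grid].
#' @param factor Positive integer block size.
#' @param aggregator `"mean"` or `"max"`.
#' @return A [suitability_grid] with dimensions `ceiling(dim / factor)` and
#'   cell size `factor * cell_size_km`.
#' @export
downsample <- function(grid, factor, aggregator = c("mean", "max")) {
  aggregator <- match.arg(aggregator)
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("`factor` must be a positive integer")
  if (factor == 1L) return(grid)
  f <- if (aggregator == "mean") mean else max
  nr <- ceiling(grid$n_rows / factor)
  nc <- ceiling(grid$n_cols / factor)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    rows <- (((i - 1L) * factor + 1L):min(i * factor, grid$n_rows))
    for (j in seq_len(nc)) {
      cols <- (((j - 1L) * factor + 1L):min(j * factor, grid$n_cols))
      out[i, j] <- f(grid$values[rows, cols])
    }
  }
  # built directly: heavy aggregation may legitimately drop below the 3x3
  # minimum the movement surface needs, e.g. when collapsing to one cell
  structure(
    list(values = out, n_rows = nr, n_cols = nc,
         cell_size_km = grid$cell_size_km * factor,
         xll = grid$xll, yll = grid$yll),
    class = "suitability_grid")
}

#' Moore neighborhood of a cell
#'
#' Returns the up-to-8 adjacent cells of `cell`, excluding the focal cell and
#' any out-of-bounds positions. The landscape is a bounded map: boundary
#' cells simply have fewer neighbors (no wraparound). Order is deterministic
#' row-major.
#'
#' @param grid A [suitability_grid].
#' @param cell Integer vector `c(row, col)`, 0-based.
#' @return Integer matrix with columns `row`, `col`, one neighbor per row.
#' @examples
#' g <- suitability_grid(matrix(0.5, 5, 5))
#' nrow(neighbors(g, c(2, 2)))  # 8
#' nrow(neighbors(g, c(0, 0)))  # 3
#' @export
neighbors <- function(grid, cell) {
  cell <- as.integer(cell)
  if (length(cell) != 2L || anyNA(cell))
    stop("`cell` must be an integer (row, col) pair")
  if (cell[1] < 0L || cell[1] >= grid$n_rows ||
      cell[2] < 0L || cell[2] >= grid$n_cols)
    stop("focal cell out of bounds")
  dr <- rep(-1:1, each = 3L)
  dc <- rep(-1:1, times = 3L)
  keep <- !(dr == 0L & dc == 0L)
  rc <- cbind(row = cell[1] + dr[keep], col = cell[2] + dc[keep])
  rc[in_bounds(grid, rc), , drop = FALSE]
}

#' Neighbors ranked by suitability
#'
#' The Moore neighborhood of `cell` sorted by suitability, highest first.
#' Ties break in row-major order so the ranking is fully deterministic;
#' stochastic exploration comes from the movement coefficient's random
#' branch, not from tie-breaking.
#'
#' @inheritParams neighbors
#' @return Integer matrix with columns `row`, `col`, best neighbor first.
#' @export
rank_neighbors <- function(grid, cell) {
  nb <- neighbors(grid, cell)
  s <- grid$values[cbind(nb[, 1L] + 1L, nb[, 2L] + 1L)]
  nb[order(-s), , drop = FALSE]  # stable sort keeps row-major order on ties
}
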