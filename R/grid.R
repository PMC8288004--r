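# Climate grids: lightweight regular lon/lat rasters held in memory, with
# ESRI ASCII grid (.asc) text I/O. Values are stored as a matrix with rows
# running south -> north (row r is centred at y0 + (r - 1/2) * cell).

#' Construct a climate grid
#'
#' A regular lon/lat raster for one climatic variable. Cell `[r, c]` is
#' centred at `(x0 + (c - 0.5) * cell, y0 + (r - 0.5) * cell)`, rows running
#' south to north.
#'
#' @param values Numeric matrix of cell values (rows = latitude bands,
#'   south to north).
#' @param x0,y0 Lower-left corner of the grid (degrees lon/lat, WGS84).
#' @param cell Cell size in degrees (> 0).
#' @param name Variable name (e.g. `"temp_mean"`).
#' @param group Variable group, `"temperature"` or `"precipitation"`.
#' @param nodata Value marking missing cells.
#' @return An object of class `climate_grid`.
#' @export
climate_grid <- function(values, x0, y0, cell, name,
                         group = c("temperature", "precipitation"),
                         nodata = -9999) {
  group <- match.arg(group)
  assert_that(is.matrix(values), "values must be a matrix")
  assert_that(cell > 0, "cell size must be positive")
  v <- values[values != nodata]
  assert_that(all(is.finite(v)), "grid values must be finite outside nodata")
  structure(list(values = values, x0 = x0, y0 = y0, cell = cell,
                 name = name, group = group, nodata = nodata),
            class = "climate_grid")
}

#' @export
print.climate_grid <- function(x, ...) {
  cat(sprintf("<climate_grid> %s [%s]: %d x %d cells, %.4g deg, origin (%.3f, %.3f)\n",
              x$name, x$group, nrow(x$values), ncol(x$values), x$cell, x$x0, x$y0))
  invisible(x)
}

#' Extent of a climate grid
#' @param g A [climate_grid].
#' @return Named vector `xmin`, `xmax`, `ymin`, `ymax`.
#' @export
grid_extent <- function(g) {
  c(xmin = g$x0, xmax = g$x0 + ncol(g$values) * g$cell,
    ymin = g$y0, ymax = g$y0 + nrow(g$values) * g$cell)
}

#' Cell-centre coordinates of a climate grid
#' @param g A [climate_grid].
#' @return List `x` (west-east), `y` (south-north) of cell centres.
#' @export
grid_cell_centres <- function(g) {
  list(x = g$x0 + (seq_len(ncol(g$values)) - 0.5) * g$cell,
       y = g$y0 + (seq_len(nrow(g$values)) - 0.5) * g$cell)
}

# Smooth seeded noise: a coarse Gaussian lattice blown up to grid resolution
# by bilinear interpolation, so neighbouring cells are correlated.
smooth_noise <- function(nr, nc, coarse = 6) {
  cz <- matrix(rnorm((coarse + 2)^2), coarse + 2, coarse + 2)
  rr <- seq(1, coarse + 1, length.out = nr)
  cc <- seq(1, coarse + 1, length.out = nc)
  ri <- floor(rr); ci <- floor(cc)
  rf <- rr - ri;  cf <- cc - ci
  out <- matrix(0, nr, nc)
  for (j in seq_len(nc)) {
    c0 <- ci[j]; f <- cf[j]
    col <- cz[cbind(ri, c0)] * (1 - rf) + cz[cbind(ri + 1L, c0)] * rf
    col2 <- cz[cbind(ri, c0 + 1L)] * (1 - rf) + cz[cbind(ri + 1L, c0 + 1L)] * rf
    out[, j] <- col * (1 - f) + col2 * f
  }
  out
}

#' Generate synthetic climate grids
#'
#' Each variable is a deterministic planar gradient across the extent plus
#' seeded smooth spatial noise. Gradient directions are configurable so that
#' temperature- and precipitation-group variables can be given any angular
#' separation, keeping the candidate drivers statistically distinguishable.
#'
#' @param extent Numeric `c(xmin, xmax, ymin, ymax)` in degrees.
#' @param cell_size Cell size in degrees (> 0).
#' @param variable_specs List of specs, each a list with `name`, `group`
#'   (`"temperature"`/`"precipitation"`), `direction` (gradient azimuth in
#'   degrees, 0 = west->east, 90 = south->north), `base` and `range`
#'   (variable units), and optional `noise` (sd of smooth noise, same units).
#' @param seed Integer seed; same seed gives identical grids.
#' @return Named list of [climate_grid] objects.
#' @export
make_climate_grid <- function(extent, cell_size, variable_specs, seed = 1) {
  assert_that(length(variable_specs) >= 1, "variable_specs must not be empty")
  assert_that(cell_size > 0, "cell size must be positive")
  assert_that(extent[2] > extent[1] && extent[4] > extent[3],
              "extent must be positive")
  nc <- max(1L, round((extent[2] - extent[1]) / cell_size))
  nr <- max(1L, round((extent[4] - extent[3]) / cell_size))
  xs <- extent[1] + (seq_len(nc) - 0.5) * cell_size
  ys <- extent[3] + (seq_len(nr) - 0.5) * cell_size
  grids <- list()
  for (i in seq_along(variable_specs)) {
    sp <- variable_specs[[i]]
    assert_that(!is.null(sp$name) && !is.null(sp$group),
                "each variable spec needs a name and a group")
    dir <- (sp$direction %||% 0) * pi / 180
    base <- sp$base %||% 0
    rng <- sp$range %||% 1
    noise <- sp$noise %||% 0
    proj <- outer(ys, xs, function(y, x) cos(dir) * x + sin(dir) * y)
    pr <- range(proj)
    vals <- if (diff(pr) > 0) base + rng * (proj - pr[1]) / diff(pr) else
      matrix(base, nr, nc)
    if (noise > 0)
      vals <- vals + noise * with_seed(sub_seed(seed, i), smooth_noise(nr, nc))
    grids[[sp$name]] <- climate_grid(vals, extent[1], extent[3], cell_size,
                                     sp$name, sp$group)
  }
  grids
}

#' Extract climate values at sample points
#'
#' Nearest-cell extraction: each point takes the value of the cell whose
#' half-open interval `[x0 + (c-1) * cell, x0 + c * cell)` contains it.
#'
#' @param grids Named list of [climate_grid] objects.
#' @param samples Data frame with columns `id`, `lon`, `lat` (and usually
#'   `population`).
#' @return A `climate_table` data frame: one row per sample (`sample_id`,
#'   then one column per variable), with variable groups in
#'   `attr(, "groups")`.
#' @export
extract_at_points <- function(grids, samples) {
  assert_that(length(grids) >= 1, "need at least one grid")
  out <- data.frame(sample_id = samples$id, stringsAsFactors = FALSE)
  for (g in grids) {
    ext <- grid_extent(g)
    col <- floor((samples$lon - g$x0) / g$cell) + 1L
    row <- floor((samples$lat - g$y0) / g$cell) + 1L
    bad <- samples$lon < ext["xmin"] | samples$lon >= ext["xmax"] |
      samples$lat < ext["ymin"] | samples$lat >= ext["ymax"]
    if (any(bad))
      stopf("samples outside extent of grid '%s': %s", g$name,
            paste(samples$id[bad], collapse = ", "))
    vals <- g$values[cbind(row, col)]
    nod <- vals == g$nodata
    if (any(nod))
      stopf("samples in nodata cells of grid '%s': %s", g$name,
            paste(samples$id[nod], collapse = ", "))
    out[[g$name]] <- vals
  }
  attr(out, "groups") <- setNames(vapply(grids, `[[`, "", "group"),
                                  vapply(grids, `[[`, "", "name"))
  class(out) <- c("climate_table", "data.frame")
  out
}

#' Write a climate grid as an ESRI ASCII grid (.asc)
#'
#' @param g A [climate_grid].
#' @param path Output file path.
#' @export
write_ascii_grid <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(g$values)),
               sprintf("nrows %d", nrow(g$values)),
               sprintf("xllcorner %.10g", g$x0),
               sprintf("yllcorner %.10g", g$y0),
               sprintf("cellsize %.10g", g$cell),
               sprintf("NODATA_value %.10g", g$nodata)), con)
  # .asc rows run north -> south
  for (r in rev(seq_len(nrow(g$values))))
    writeLines(paste(formatC(g$values[r, ], format = "g", digits = 10),
                     collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid (.asc)
#'
#' @param path File path.
#' @param name Variable name to assign.
#' @param group Variable group.
#' @return A [climate_grid].
#' @export
read_ascii_grid <- function(path, name = basename(path),
                            group = c("temperature", "precipitation")) {
  group <- match.arg(group)
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  kv <- setNames(as.numeric(vapply(hdr, `[`, "", 2)),
                 vapply(hdr, `[`, "", 1))
  vals <- do.call(rbind, lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  vals <- vals[rev(seq_len(nrow(vals))), , drop = FALSE]  # back to S -> N
  climate_grid(vals, kv[["xllcorner"]], kv[["yllcorner"]], kv[["cellsize"]],
               name, group, nodata = kv[["nodata_value"]])
}
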