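# Spatial projection of fitted GDMs: climate layers transformed into
# genetic-importance surfaces, PCA-composited RGB maps of predicted genetic
# composition, and Procrustes comparison of composition maps.

#' Transform climate grids into genetic-importance surfaces
#'
#' For each climate predictor retained in the model, every cell value `x`
#' becomes the fitted turnover height `f_p(x) = sum_k beta_pk I_pk(x)`
#' (clamped to the training range). The geographic predictor is not mapped.
#'
#' @param model A `gdm_model`.
#' @param climate_grids Named list of [climate_grid]s covering the model's
#'   climate predictors.
#' @return Named list of [climate_grid] surfaces (genetic-importance
#'   units); nodata propagated.
#' @export
transform_grid <- function(model, climate_grids) {
  preds <- setdiff(model$predictors, "geographic")
  assert_that(length(preds) >= 1, "model has no climate predictors to map")
  missing <- setdiff(preds, names(climate_grids))
  if (length(missing) > 0)
    stopf("no grid for model predictor(s): %s", paste(missing, collapse = ", "))
  out <- list()
  for (p in preds) {
    g <- climate_grids[[p]]
    vals <- g$values
    ok <- vals != g$nodata
    f <- eval_ispline(model$bases[[p]], vals[ok]) %*% model$coef[, p]
    vals[ok] <- as.numeric(f)
    out[[p]] <- climate_grid(vals, g$x0, g$y0, g$cell, p, g$group, g$nodata)
  }
  out
}

#' Composite importance surfaces into a PCA/RGB genetic-composition map
#'
#' Cells are rows, surfaces columns; the matrix is centred and reduced by
#' PCA to three components (zero-padded when fewer surfaces exist); each
#' channel is min-max scaled to `[0, 255]` (R = PC1, G = PC2, B = PC3).
#' Similar colours mean similar predicted genetic composition.
#'
#' @param surfaces Named list of importance surfaces from [transform_grid()].
#' @return A `composition_map`: `pcs` (cells x 3 score matrix), `rgb`
#'   (rows x cols x 3 array in 0-255), `loadings`, `cell_ok` (logical mask),
#'   and the template grid.
#' @export
pca_rgb <- function(surfaces) {
  assert_that(length(surfaces) >= 1, "need at least one surface")
  g0 <- surfaces[[1]]
  M <- sapply(surfaces, function(s) as.vector(s$values))
  M <- matrix(M, ncol = length(surfaces),
              dimnames = list(NULL, names(surfaces)))
  ok <- rowSums(matrix(sapply(surfaces, function(s)
    as.vector(s$values) == s$nodata), ncol = length(surfaces))) == 0
  sds <- apply(M[ok, , drop = FALSE], 2, sd)
  if (all(sds == 0)) stopf("all surfaces constant; PCA undefined")
  pc <- prcomp(M[ok, , drop = FALSE], center = TRUE, scale. = FALSE)
  k <- min(3, ncol(pc$x))
  pcs <- matrix(0, sum(ok), 3)
  pcs[, seq_len(k)] <- pc$x[, seq_len(k), drop = FALSE]
  rgb_arr <- array(0, dim = c(nrow(g0$values), ncol(g0$values), 3))
  for (ch in 1:3) {
    v <- pcs[, ch]
    scaled <- if (diff(range(v)) > 0)
      255 * (v - min(v)) / diff(range(v)) else rep(0, length(v))
    layer <- matrix(NA_real_, nrow(g0$values), ncol(g0$values))
    layer[ok] <- scaled
    rgb_arr[, , ch] <- layer
  }
  structure(list(pcs = pcs, rgb = rgb_arr,
                 loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 sdev = pc$sdev, cell_ok = ok, template = g0),
            class = "composition_map")
}

#' @export
print.composition_map <- function(x, ...) {
  cat(sprintf("<composition_map> %d cells, %d surfaces -> 3 PCs\n",
              sum(x$cell_ok), nrow(x$loadings)))
  invisible(x)
}

#' Write the RGB composite of a composition map as PNG
#' @param map A `composition_map`.
#' @param path Output path.
#' @export
write_composition_png <- function(map, path) {
  img <- map$rgb / 255
  img[is.na(img)] <- 0
  img <- img[rev(seq_len(dim(img)[1])), , , drop = FALSE]  # north up
  png::writePNG(img, path)
  invisible(path)
}

#' Procrustes comparison of two genetic-composition maps
#'
#' Least-squares superimposition of the target's cell x 3 PC configuration
#' onto the reference's (translation, rotation and uniform scaling;
#' reflections permitted since PC signs are arbitrary). The residual per
#' cell is the Euclidean distance between matched points after
#' superimposition.
#'
#' @param map_ref,map_target `composition_map`s on identical cell sets.
#' @return A `procrustes_result`: `rotation`, `scale`, `translation`,
#'   `residuals` (per cell), `rss`.
#' @export
procrustes_residuals <- function(map_ref, map_target) {
  ok_r <- map_ref$cell_ok; ok_t <- map_target$cell_ok
  if (!identical(ok_r, ok_t)) stopf("maps defined on different cell sets")
  X <- map_ref$pcs
  Y <- map_target$pcs
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  sv <- svd(crossprod(Yc, Xc))
  rot <- sv$u %*% t(sv$v)
  ssy <- sum(Yc^2)
  s <- if (ssy > 0) sum(sv$d) / ssy else 1
  fitted <- s * Yc %*% rot
  resid <- sqrt(rowSums((Xc - fitted)^2))
  structure(list(rotation = rot, scale = s,
                 translation = cx - s * as.numeric(cy %*% rot),
                 residuals = resid, rss = sum((Xc - fitted)^2),
                 cell_ok = ok_r, template = map_ref$template),
            class = "procrustes_result")
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat(sprintf("<procrustes_result> %d cells, scale %.3f, RSS %.4g\n",
              length(x$residuals), x$scale, x$rss))
  invisible(x)
}

#' Scale two residual sets jointly onto [0, 1]
#'
#' Residuals are scaled by the largest and smallest value observed across
#' both inputs, so the two sets remain directly comparable.
#'
#' @param residuals_a,residuals_b Numeric residual vectors (non-empty).
#' @return List `a`, `b` of scaled residuals plus the pooled `min`/`max`.
#' @export
scale_residuals_across <- function(residuals_a, residuals_b) {
  assert_that(length(residuals_a) > 0 && length(residuals_b) > 0,
              "residual sets must be non-empty")
  lo <- min(residuals_a, residuals_b)
  hi <- max(residuals_a, residuals_b)
  if (hi == lo) stopf("pooled residual range is degenerate")
  list(a = (residuals_a - lo) / (hi - lo),
       b = (residuals_b - lo) / (hi - lo), min = lo, max = hi)
}

#' Residuals of a Procrustes result as a grid for mapping
#' @param pr A `procrustes_result`.
#' @param residuals Optionally externally scaled residuals to place.
#' @return A [climate_grid] of residual values.
#' @export
residual_grid <- function(pr, residuals = NULL) {
  g0 <- pr$template
  vals <- matrix(g0$nodata, nrow(g0$values), ncol(g0$values))
  vals[pr$cell_ok] <- residuals %||% pr$residuals
  climate_grid(vals, g0$x0, g0$y0, g0$cell, "procrustes_residuals",
               g0$group, g0$nodata)
}
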