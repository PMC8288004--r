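# Generalized dissimilarity modelling: monotone I-spline regression of a
# scaled dissimilarity on predictor differences through the negative
# exponential link mu = 1 - exp(-eta), fitted by iteratively reweighted
# non-negative least squares on the binomial-type deviance. Includes
# permutation-based backward elimination, predictor importance, and
# deviance partitioning by predictor group.

#' Order-2 monotone I-spline basis with knots at the 0/50/100th percentiles
#'
#' Three nondecreasing basis functions, each 0 at the predictor minimum and
#' 1 at the maximum; values outside the observed range clamp to 0/1. These
#' are the integrals of the order-2 M-splines on the knot sequence
#' `{t1, t1, t2, t3, t3}`.
#'
#' @param x_values Observed site values (>= 3 distinct).
#' @param n_splines Number of splines; only 3 supported.
#' @return An `ispline_basis` with `knots` and an evaluator.
#' @export
ispline_basis <- function(x_values, n_splines = 3) {
  assert_that(n_splines == 3, "only 3 splines are supported")
  x <- x_values[!is.na(x_values)]
  assert_that(length(unique(x)) >= 3, "need at least 3 distinct site values")
  kn <- unname(quantile(x, c(0, 0.5, 1)))
  if (kn[2] <= kn[1] || kn[2] >= kn[3]) kn[2] <- (kn[1] + kn[3]) / 2
  structure(list(knots = kn), class = "ispline_basis")
}

#' Evaluate an I-spline basis
#'
#' @param basis An [ispline_basis].
#' @param x Values at which to evaluate (clamped to the knot range).
#' @return Matrix `length(x) x 3` of basis values.
#' @export
eval_ispline <- function(basis, x) {
  t1 <- basis$knots[1]; t2 <- basis$knots[2]; t3 <- basis$knots[3]
  x <- pmin(pmax(x, t1), t3)
  b <- matrix(0, length(x), 3)
  lo <- x <= t2
  # I1: integral of the descending M-spline on [t1, t1, t2]
  b[lo, 1] <- 1 - (t2 - x[lo])^2 / (t2 - t1)^2
  b[!lo, 1] <- 1
  # I2: integral of the hat M-spline on [t1, t2, t3]
  b[lo, 2] <- (x[lo] - t1)^2 / ((t2 - t1) * (t3 - t1))
  b[!lo, 2] <- 1 - (t3 - x[!lo])^2 / ((t3 - t2) * (t3 - t1))
  # I3: integral of the ascending M-spline on [t2, t3, t3]
  b[!lo, 3] <- (x[!lo] - t2)^2 / (t3 - t2)^2
  b
}

#' Assemble a site-pair table from a scaled dissimilarity matrix
#'
#' One row per unordered population pair, with the observed dissimilarity,
#' each predictor's two site values, and the great-circle (Haversine)
#' geographic distance in km between population centroids.
#'
#' @param scaled_fst Square dissimilarity matrix in `[0, 1]` with
#'   population row/col names (e.g. from [scale_unit()]).
#' @param pop_predictors Population x variable predictor matrix (row names
#'   matching the dissimilarity labels).
#' @param pop_coords Population x `lon`/`lat` centroid matrix.
#' @return A `site_pair_table`: `pairs` data frame (`site1`, `site2`, `d`,
#'   `distance_km`), `pred` (site x predictor matrix incl. `geographic`
#'   holding zeros), and bookkeeping.
#' @export
build_pair_table <- function(scaled_fst, pop_predictors, pop_coords) {
  m <- as.matrix(scaled_fst)
  pops <- rownames(m)
  assert_that(!is.null(pops), "dissimilarity matrix needs row names")
  if (!all(pops %in% rownames(pop_predictors)))
    stopf("predictor matrix labels do not match dissimilarity labels")
  if (!all(pops %in% rownames(pop_coords)))
    stopf("coordinate labels do not match dissimilarity labels")
  pop_predictors <- pop_predictors[pops, , drop = FALSE]
  pop_coords <- pop_coords[pops, , drop = FALSE]
  cmb <- utils::combn(length(pops), 2)
  dist_km <- apply(cmb, 2, function(ij)
    geosphere::distHaversine(pop_coords[ij[1], c("lon", "lat")],
                             pop_coords[ij[2], c("lon", "lat")]) / 1000)
  pairs <- data.frame(site1 = pops[cmb[1, ]], site2 = pops[cmb[2, ]],
                      d = m[t(cmb)], distance_km = dist_km,
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs, pred = pop_predictors, coords = pop_coords,
                 pops = pops), class = "site_pair_table")
}

# Design matrix of |I(x_i) - I(x_j)| columns (and I(distance) for the
# geographic predictor) for the given predictors and bases.
gdm_design <- function(pt, predictors, bases) {
  cmb <- cbind(match(pt$pairs$site1, pt$pops), match(pt$pairs$site2, pt$pops))
  cols <- list()
  for (p in predictors) {
    if (p == "geographic") {
      cols[[p]] <- eval_ispline(bases[[p]], pt$pairs$distance_km)
    } else {
      B <- eval_ispline(bases[[p]], pt$pred[, p])
      cols[[p]] <- abs(B[cmb[, 1], , drop = FALSE] - B[cmb[, 2], , drop = FALSE])
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- paste(rep(predictors, each = 3), 1:3, sep = "_s")
  cbind(intercept = 1, X)
}

gdm_bases <- function(pt, predictors) {
  bases <- list()
  for (p in predictors) {
    bases[[p]] <- if (p == "geographic")
      ispline_basis(pt$pairs$distance_km) else ispline_basis(pt$pred[, p])
  }
  bases
}

#' Fit a generalized dissimilarity model
#'
#' The linear predictor is
#' `eta = a0 + sum_p sum_k beta_pk |I_pk(x_pi) - I_pk(x_pj)|` with all
#' coefficients (including the intercept) non-negative, fitted by
#' iteratively reweighted non-negative least squares minimizing the
#' binomial-type deviance of `d` against `mu = 1 - exp(-eta)`. Percent
#' deviance explained is relative to the intercept-only null.
#'
#' @param pair_table A `site_pair_table`.
#' @param predictors Predictor names (`"geographic"` plus columns of
#'   `pair_table$pred`); default all.
#' @param bases Optional named list of [ispline_basis] objects (defaults
#'   computed from the table's site values).
#' @param maxit,tol IRLS controls.
#' @return A `gdm_model`: `intercept`, `coef` (3 x predictor matrix),
#'   `knots`, `deviance`, `null_deviance`, `pct_explained`, `fitted`.
#' @export
fit_gdm <- function(pair_table, predictors = NULL, bases = NULL,
                    maxit = 100, tol = 1e-6) {
  pt <- pair_table
  predictors <- predictors %||% c("geographic", colnames(pt$pred))
  n_pairs <- nrow(pt$pairs)
  if (n_pairs < 3 * length(predictors) + 1)
    warning("fewer pairs than recommended for ", length(predictors),
            " predictors")
  bases <- bases %||% gdm_bases(pt, predictors)
  X <- gdm_design(pt, predictors, bases)
  d <- pt$pairs$d
  fit <- gdm_irls_cpp(X, d, maxit, tol)
  if (!fit$converged)
    stopf("GDM IRLS failed to converge within %d iterations (deviance %.6g)",
          maxit, fit$deviance)
  null_fit <- gdm_irls_cpp(matrix(1, n_pairs, 1), d, maxit, tol)
  # numerically perfect fits can give deviance ~ -1e-10 via the mu clamp
  fit$deviance <- max(fit$deviance, 0)
  beta <- as.numeric(fit$beta)
  coef_mat <- matrix(beta[-1], nrow = 3,
                     dimnames = list(paste0("s", 1:3), predictors))
  structure(list(intercept = beta[1], coef = coef_mat,
                 bases = bases, predictors = predictors,
                 deviance = fit$deviance, null_deviance = null_fit$deviance,
                 pct_explained = 100 * (1 - fit$deviance / null_fit$deviance),
                 fitted = as.numeric(fit$fitted), pair_table = pt),
            class = "gdm_model")
}

#' @export
print.gdm_model <- function(x, ...) {
  cat(sprintf("<gdm_model> %s; deviance %.3f (null %.3f), %.1f%% explained\n",
              paste(x$predictors, collapse = " + "), x$deviance,
              x$null_deviance, x$pct_explained))
  invisible(x)
}

#' Predict pair dissimilarities from a fitted GDM
#' @param object A `gdm_model`.
#' @param pair_table Optional new `site_pair_table` (default: training).
#' @param ... Unused.
#' @return Predicted dissimilarities in `[0, 1)`.
#' @export
predict.gdm_model <- function(object, pair_table = NULL, ...) {
  pt <- pair_table %||% object$pair_table
  X <- gdm_design(pt, object$predictors, object$bases)
  eta <- as.numeric(X %*% c(object$intercept, as.numeric(object$coef)))
  1 - exp(-eta)
}

#' Predictor importance: summed spline coefficients
#'
#' @param model A `gdm_model`.
#' @return Named vector `sum_k beta_pk` per retained predictor (also the
#'   maximum height of the fitted turnover curve).
#' @export
gdm_importance <- function(model) {
  colSums(model$coef)
}

#' Sample fitted turnover curves for plotting
#' @param model A `gdm_model`.
#' @param n Points per curve.
#' @return Data frame `predictor`, `x`, `f` of fitted spline heights.
#' @export
gdm_splines <- function(model, n = 200) {
  out <- list()
  for (p in model$predictors) {
    kn <- model$bases[[p]]$knots
    xs <- seq(kn[1], kn[3], length.out = n)
    f <- as.numeric(eval_ispline(model$bases[[p]], xs) %*% model$coef[, p])
    out[[p]] <- data.frame(predictor = p, x = xs, f = f)
  }
  do.call(rbind, out)
}

# permutation p-values for each predictor of a fitted model: site-level
# permutation of the predictor's values, pair table rebuilt, model refit,
# compared on percent deviance explained.
gdm_perm_pvalues <- function(pt, predictors, bases, observed_pct, n_perm,
                             seed) {
  n_sites <- length(pt$pops)
  pv <- setNames(numeric(length(predictors)), predictors)
  for (p in predictors) {
    beats <- with_seed(sub_seed(seed, 700 + match(p, predictors)), {
      cnt <- 0
      for (b in seq_len(n_perm)) {
        perm <- sample.int(n_sites)
        pt2 <- pt
        if (p == "geographic") {
          pt2$coords <- pt$coords[perm, , drop = FALSE]
          rownames(pt2$coords) <- pt$pops
          d1 <- match(pt$pairs$site1, pt$pops)
          d2 <- match(pt$pairs$site2, pt$pops)
          pt2$pairs$distance_km <- apply(cbind(d1, d2), 1, function(ij)
            geosphere::distHaversine(pt2$coords[ij[1], c("lon", "lat")],
                                     pt2$coords[ij[2], c("lon", "lat")]) / 1000)
        } else {
          pt2$pred[, p] <- pt$pred[perm, p]
        }
        X <- gdm_design(pt2, predictors, bases)
        fit <- gdm_irls_cpp(X, pt2$pairs$d, 100, 1e-6)
        null_dev <- gdm_irls_cpp(matrix(1, nrow(X), 1), pt2$pairs$d,
                                 100, 1e-6)$deviance
        pct <- 100 * (1 - fit$deviance / null_dev)
        if (pct >= observed_pct) cnt <- cnt + 1
      }
      cnt
    })
    pv[p] <- (beats + 1) / (n_perm + 1)
  }
  pv
}

#' Backward elimination of GDM predictors by permutation significance
#'
#' Each predictor's p-value is the proportion of site-level permutations of
#' its values (pair table rebuilt, model refit) whose percent deviance
#' explained reaches the observed model's. While any retained predictor is
#' non-significant, the non-significant predictor with the smallest summed
#' coefficients is removed (ties by input order) and the model refitted.
#' Named predictors can be force-retained regardless of significance.
#'
#' @param pair_table A `site_pair_table`.
#' @param predictors Starting predictor set (default all).
#' @param n_perm Permutations per predictor (default 500).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed.
#' @param force_retain Predictor names never eliminated.
#' @return The final `gdm_model` with `$perm_pvalues`; an intercept-only
#'   model (with a warning) if everything is eliminated.
#' @export
backward_eliminate <- function(pair_table, predictors = NULL, n_perm = 500,
                               alpha = 0.05, seed = 1, force_retain = NULL) {
  pt <- pair_table
  preds <- predictors %||% c("geographic", colnames(pt$pred))
  input_order <- preds
  bases <- gdm_bases(pt, preds)
  round <- 0
  repeat {
    round <- round + 1
    model <- fit_gdm(pt, preds, bases[preds])
    pv <- gdm_perm_pvalues(pt, preds, bases[preds], model$pct_explained,
                           n_perm, sub_seed(seed, round))
    nonsig <- setdiff(preds[pv > alpha], force_retain)
    if (length(nonsig) == 0) {
      model$perm_pvalues <- pv
      return(model)
    }
    imp <- gdm_importance(model)[nonsig]
    weakest <- nonsig[imp <= min(imp) + 1e-12]
    drop <- weakest[which.min(match(weakest, input_order))]
    preds <- setdiff(preds, drop)
    if (length(preds) == 0) {
      warning("all predictors eliminated; returning intercept-only model")
      null_fit <- gdm_irls_cpp(matrix(1, nrow(pt$pairs), 1), pt$pairs$d,
                               100, 1e-6)
      return(structure(list(intercept = as.numeric(null_fit$beta),
                            coef = matrix(numeric(0), 3, 0), bases = list(),
                            predictors = character(0),
                            deviance = null_fit$deviance,
                            null_deviance = null_fit$deviance,
                            pct_explained = 0,
                            fitted = as.numeric(null_fit$fitted),
                            pair_table = pt, perm_pvalues = pv),
                       class = "gdm_model"))
    }
  }
}

#' Partition GDM explained deviance by predictor group
#'
#' Fits GDMs on every non-empty subset of the groups and decomposes the
#' explained-deviance fractions by inclusion-exclusion into unique and
#' joint components, expressed as percentages of the full model's explained
#' deviance. Small negative components (> -1 percentage point) are clamped
#' to zero with a message; larger negatives are reported as-is.
#'
#' @param pair_table A `site_pair_table`.
#' @param groups Named list mapping group name (e.g. `geographic`,
#'   `temperature`, `precipitation`) to predictor names; empty groups are
#'   dropped.
#' @return A `deviance_partition`: data frame of components (`component`,
#'   `percent`, raw `percent_raw`), plus the subset percent-explained table
#'   and the full model's `pct_explained`.
#' @export
partition_deviance <- function(pair_table, groups) {
  groups <- groups[vapply(groups, length, 1L) > 0]
  gnames <- names(groups)
  assert_that(length(gnames) >= 1, "no non-empty predictor groups")
  assert_that(length(gnames) <= 3, "at most three groups supported")
  pt <- pair_table
  subsets <- unlist(lapply(seq_along(gnames), function(k)
    utils::combn(gnames, k, simplify = FALSE)), recursive = FALSE)
  E <- setNames(numeric(length(subsets)),
                vapply(subsets, paste, "", collapse = "+"))
  for (s in subsets) {
    preds <- unlist(groups[s], use.names = FALSE)
    E[paste(s, collapse = "+")] <- fit_gdm(pt, preds)$pct_explained
  }
  full_key <- paste(gnames, collapse = "+")
  full <- E[full_key]
  comp <- c()
  if (length(gnames) == 1) {
    comp[paste0("unique_", gnames)] <- E[gnames]
  } else if (length(gnames) == 2) {
    A <- gnames[1]; B <- gnames[2]
    comp[paste0("unique_", A)] <- full - E[B]
    comp[paste0("unique_", B)] <- full - E[A]
    comp[paste0("joint_", A, "_", B)] <- E[A] + E[B] - full
  } else {
    A <- gnames[1]; B <- gnames[2]; C <- gnames[3]
    k <- function(...) paste(c(...), collapse = "+")
    g3 <- E[A] + E[B] + E[C] - E[k(A, B)] - E[k(A, C)] - E[k(B, C)] + full
    comp[paste0("unique_", A)] <- full - E[k(B, C)]
    comp[paste0("unique_", B)] <- full - E[k(A, C)]
    comp[paste0("unique_", C)] <- full - E[k(A, B)]
    comp[paste0("joint_", A, "_", B)] <- E[k(A, C)] + E[k(B, C)] - E[C] - full
    comp[paste0("joint_", A, "_", C)] <- E[k(A, B)] + E[k(B, C)] - E[B] - full
    comp[paste0("joint_", B, "_", C)] <- E[k(A, B)] + E[k(A, C)] - E[A] - full
    comp[paste0("joint_", A, "_", B, "_", C)] <- g3
  }
  if (full <= 0) stopf("full model explains no deviance")
  raw <- 100 * comp / full
  clamped <- raw
  small_neg <- raw < 0 & raw > -1
  if (any(small_neg)) {
    message("clamped ", sum(small_neg),
            " small negative partition component(s) to 0")
    clamped[small_neg] <- 0
  }
  structure(list(components = data.frame(component = names(raw),
                                         percent = unname(clamped),
                                         percent_raw = unname(raw),
                                         stringsAsFactors = FALSE),
                 subset_pct_explained = E, pct_explained = unname(full),
                 groups = groups),
            class = "deviance_partition")
}

#' @export
print.deviance_partition <- function(x, ...) {
  cat(sprintf("<deviance_partition> full model %.1f%% explained\n",
              x$pct_explained))
  print(x$components[c("component", "percent")], row.names = FALSE)
  invisible(x)
}

#' Total deviance share of a predictor group (unique plus joint components)
#' @param partition A `deviance_partition`.
#' @param group Group name.
#' @return Percent of explained deviance involving the group.
#' @export
group_share <- function(partition, group) {
  comp <- partition$components
  involved <- grepl(paste0("(^unique_", group, "$)|(_", group, "(_|$))"),
                    comp$component)
  sum(comp$percent[involved])
}
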