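# Generalized dissimilarity modelling: spline basis, fitting, elimination,
# deviance partitioning.

# small deterministic landscape of sites with two predictors
mk_sites <- function(n_sites = 12, seed = 5) {
  withr::with_seed(seed, {
    pops <- sprintf("P%02d", seq_len(n_sites))
    pred <- cbind(v1 = sort(runif(n_sites, 0, 10)),
                  v2 = runif(n_sites, 0, 5))
    rownames(pred) <- pops
    coords <- cbind(lon = runif(n_sites, 116, 120),
                    lat = runif(n_sites, -30, -27))
    rownames(coords) <- pops
    list(pops = pops, pred = pred, coords = coords)
  })
}

# dissimilarities generated from a known monotone model on v1
mk_known_pt <- function(sites, coefs = c(0.5, 0.8, 0.3), a0 = 0.2) {
  b1 <- ispline_basis(sites$pred[, "v1"])
  f <- function(x) as.numeric(eval_ispline(b1, x) %*% coefs)
  n <- length(sites$pops)
  cmb <- utils::combn(n, 2)
  d <- 1 - exp(-(a0 + abs(f(sites$pred[cmb[1, ], "v1"]) -
                            f(sites$pred[cmb[2, ], "v1"]))))
  m <- matrix(0, n, n, dimnames = list(sites$pops, sites$pops))
  m[t(cmb)] <- d
  m <- m + t(m)
  build_pair_table(m, sites$pred, sites$coords)
}

test_that("I-spline basis is 0 at the minimum, 1 at the maximum, monotone", {
  b <- ispline_basis(c(0, 1, 2, 5, 10))
  expect_equal(as.numeric(eval_ispline(b, 0)), c(0, 0, 0))
  expect_equal(as.numeric(eval_ispline(b, 10)), c(1, 1, 1))
  xs <- seq(0, 10, length.out = 200)
  B <- eval_ispline(b, xs)
  expect_true(all(diff(B[, 1]) >= 0 & diff(B[, 2]) >= 0 & diff(B[, 3]) >= 0))
  # clamping outside the range
  expect_equal(as.numeric(eval_ispline(b, -5)), c(0, 0, 0))
  expect_equal(as.numeric(eval_ispline(b, 50)), c(1, 1, 1))
  expect_error(ispline_basis(c(1, 1, 1)), "distinct")
})

test_that("I-splines integrate their M-splines (numeric-integration oracle)", {
  b <- ispline_basis(c(0, 2, 3, 7, 10))
  t1 <- b$knots[1]; t2 <- b$knots[2]; t3 <- b$knots[3]
  # order-2 M-splines on {t1,t1,t2}, {t1,t2,t3}, {t2,t3,t3}
  M <- list(function(x) ifelse(x <= t2, 2 * (t2 - x) / (t2 - t1)^2, 0),
            function(x) ifelse(x <= t2, 2 * (x - t1) / ((t3 - t1) * (t2 - t1)),
                               2 * (t3 - x) / ((t3 - t1) * (t3 - t2))),
            function(x) ifelse(x <= t2, 0, 2 * (x - t2) / (t3 - t2)^2))
  xs <- seq(t1, t3, length.out = 100)
  for (k in 1:3) {
    closed <- eval_ispline(b, xs)[, k]
    numeric <- vapply(xs, function(xx)
      integrate(M[[k]], t1, xx, rel.tol = 1e-10)$value, numeric(1))
    expect_lt(max(abs(closed - numeric)), 1e-6)
  }
})

test_that("pair table covers all pairs with great-circle distances", {
  sites <- mk_sites(4)
  m <- matrix(0.5, 4, 4, dimnames = list(sites$pops, sites$pops))
  diag(m) <- 0
  pt <- build_pair_table(m, sites$pred, sites$coords)
  expect_equal(nrow(pt$pairs), 6)
  # two points one degree apart on the equator
  coords <- cbind(lon = c(0, 1), lat = c(0, 0))
  rownames(coords) <- c("a", "b")
  m2 <- matrix(c(0, .5, .5, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  pred <- cbind(v = c(1, 2)); rownames(pred) <- c("a", "b")
  pt2 <- build_pair_table(m2, pred, coords)
  expect_equal(pt2$pairs$distance_km, 111.19, tolerance = 0.5 / 111.19)
  # coincident populations at distance zero
  coords[2, ] <- coords[1, ]
  pt3 <- build_pair_table(m2, pred, coords)
  expect_equal(pt3$pairs$distance_km, 0)
  expect_error(build_pair_table(m2, pred[1, , drop = FALSE], coords),
               "labels")
})

test_that("all-zero coefficients predict zero dissimilarity via the link", {
  sites <- mk_sites(6)
  pt <- mk_known_pt(sites)
  model <- fit_gdm(pt, predictors = "v1")
  model$intercept <- 0
  model$coef[] <- 0
  expect_equal(predict(model), rep(0, nrow(pt$pairs)))
})

test_that("noiseless dissimilarities are refit essentially exactly", {
  sites <- mk_sites(12)
  pt <- mk_known_pt(sites, coefs = c(0.5, 0.8, 0.3), a0 = 0.2)
  fit <- fit_gdm(pt, predictors = "v1")
  expect_gt(fit$pct_explained, 99)
  expect_lt(max(abs(predict(fit) - pt$pairs$d)), 1e-3)
  # summed coefficients recovered within 5%
  expect_equal(unname(gdm_importance(fit)["v1"]), 1.6, tolerance = 0.05)
})

test_that("fitted dissimilarity is monotone in predictor differences", {
  sites <- mk_sites(10, seed = 7)
  pt <- mk_known_pt(sites)
  fit <- fit_gdm(pt, predictors = c("v1", "v2"))
  expect_true(all(fit$fitted >= 0 & fit$fitted < 1))
  expect_true(all(as.numeric(fit$coef) >= 0) && fit$intercept >= 0)
  # increasing a single predictor difference never decreases the prediction
  b <- fit$bases[["v1"]]
  grid_x <- seq(b$knots[1], b$knots[3], length.out = 50)
  f <- as.numeric(eval_ispline(b, grid_x) %*% fit$coef[, "v1"])
  expect_true(all(diff(f) >= -1e-12))
})

test_that("adding predictors never lowers percent explained", {
  sites <- mk_sites(11, seed = 9)
  pt <- mk_known_pt(sites)
  f1 <- fit_gdm(pt, predictors = "v1")
  f2 <- fit_gdm(pt, predictors = c("v1", "v2"))
  f3 <- fit_gdm(pt, predictors = c("v1", "v2", "geographic"))
  expect_gte(f2$pct_explained, f1$pct_explained - 1e-6)
  expect_gte(f3$pct_explained, f2$pct_explained - 1e-6)
})

test_that("backward elimination drops noise and keeps the generator", {
  kept_gen <- 0; dropped_noise <- 0
  for (s in 1:5) {
    sites <- mk_sites(12, seed = 100 + s)
    pt <- mk_known_pt(sites)
    fit <- backward_eliminate(pt, predictors = c("v1", "v2"), n_perm = 100,
                              seed = s)
    if ("v1" %in% fit$predictors) kept_gen <- kept_gen + 1
    if (!("v2" %in% fit$predictors)) dropped_noise <- dropped_noise + 1
  }
  expect_equal(kept_gen, 5)
  expect_gte(dropped_noise, 4)
})

test_that("permutation p-values are deterministic and floor at 1/(n+1)", {
  sites <- mk_sites(12, seed = 3)
  pt <- mk_known_pt(sites)
  f1 <- backward_eliminate(pt, predictors = "v1", n_perm = 500, seed = 11)
  f2 <- backward_eliminate(pt, predictors = "v1", n_perm = 500, seed = 11)
  expect_identical(f1$perm_pvalues, f2$perm_pvalues)
  expect_lte(f1$perm_pvalues[["v1"]], 0.002)
})

test_that("force-retained predictors survive elimination", {
  sites <- mk_sites(12, seed = 4)
  pt <- mk_known_pt(sites)
  fit <- backward_eliminate(pt, predictors = c("v1", "v2"), n_perm = 100,
                            seed = 2, force_retain = "v2")
  expect_true("v2" %in% fit$predictors)
})

test_that("deviance partition satisfies the inclusion-exclusion identity", {
  sites <- mk_sites(12, seed = 6)
  pt <- mk_known_pt(sites)
  part <- partition_deviance(pt, list(geographic = "geographic",
                                      temperature = "v1",
                                      precipitation = "v2"))
  expect_equal(sum(part$components$percent_raw), 100, tolerance = 1e-9)
  # single group: everything unique
  p1 <- partition_deviance(pt, list(temperature = "v1"))
  expect_equal(p1$components$percent, 100)
  # two groups
  p2 <- partition_deviance(pt, list(temperature = "v1",
                                    precipitation = "v2"))
  expect_equal(sum(p2$components$percent_raw), 100, tolerance = 1e-9)
})

test_that("orthogonal generators give near-disjoint unique components", {
  # construct a design whose pair-level turnover contributions are
  # empirically uncorrelated: pick the x2 assignment minimizing the
  # correlation of the two predictors' pair differences
  n <- 14
  pops <- sprintf("P%02d", 1:n)
  withr::with_seed(21, {
    x1 <- runif(n, 0, 10)
    x2_base <- runif(n, 0, 5)
    cmb <- utils::combn(n, 2)
    b1 <- ispline_basis(x1)
    f1 <- function(x) as.numeric(eval_ispline(b1, x) %*% c(0.4, 0.4, 0.2))
    a1 <- abs(f1(x1[cmb[1, ]]) - f1(x1[cmb[2, ]]))
    best <- NULL; best_cor <- Inf
    for (i in 1:300) {
      x2 <- sample(x2_base)
      b2 <- ispline_basis(x2)
      f2v <- as.numeric(eval_ispline(b2, x2) %*% c(0.3, 0.3, 0.2))
      a2 <- abs(f2v[cmb[1, ]] - f2v[cmb[2, ]])
      if (abs(cor(a1, a2)) < best_cor) {
        best_cor <- abs(cor(a1, a2)); best <- x2
      }
    }
    x2 <- best
    coords <- cbind(lon = runif(n, 0, 1), lat = runif(n, 0, 1))
  })
  rownames(coords) <- pops
  pred <- cbind(v1 = x1, v2 = x2); rownames(pred) <- pops
  b2 <- ispline_basis(x2)
  f2 <- function(x) as.numeric(eval_ispline(b2, x) %*% c(0.3, 0.3, 0.2))
  d <- 1 - exp(-(0.1 + abs(f1(x1[cmb[1, ]]) - f1(x1[cmb[2, ]])) +
                   abs(f2(x2[cmb[1, ]]) - f2(x2[cmb[2, ]]))))
  m <- matrix(0, n, n, dimnames = list(pops, pops))
  m[t(cmb)] <- d; m <- m + t(m)
  pt <- build_pair_table(m, pred, coords)
  part <- partition_deviance(pt, list(temperature = "v1",
                                      precipitation = "v2"))
  comp <- setNames(part$components$percent_raw, part$components$component)
  expect_gt(comp[["unique_temperature"]], 10)
  expect_gt(comp[["unique_precipitation"]], 10)
  expect_lt(abs(comp[["joint_temperature_precipitation"]]), 5)
})
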