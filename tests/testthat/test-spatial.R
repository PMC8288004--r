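# Surface transformation, PCA/RGB composition maps, Procrustes residuals.

mk_model_on_grid <- function(seed = 5) {
  # fit a one-predictor model whose basis spans the grid's value range
  g <- make_climate_grid(c(0, 5, 0, 5), 0.5,
                         list(list(name = "temp_mean", group = "temperature",
                                   direction = 0, base = 0, range = 10,
                                   noise = 0.2)), seed = seed)$temp_mean
  sites <- withr::with_seed(seed, {
    pops <- sprintf("P%02d", 1:10)
    pred <- cbind(temp_mean = seq(min(g$values), max(g$values),
                                  length.out = 10))
    rownames(pred) <- pops
    coords <- cbind(lon = runif(10, 0, 5), lat = runif(10, 0, 5))
    rownames(coords) <- pops
    list(pops = pops, pred = pred, coords = coords)
  })
  b <- ispline_basis(sites$pred[, 1])
  f <- function(x) as.numeric(eval_ispline(b, x) %*% c(0.5, 0.4, 0.3))
  cmb <- utils::combn(10, 2)
  d <- 1 - exp(-(0.1 + abs(f(sites$pred[cmb[1, ], 1]) -
                             f(sites$pred[cmb[2, ], 1]))))
  m <- matrix(0, 10, 10, dimnames = list(sites$pops, sites$pops))
  m[t(cmb)] <- d; m <- m + t(m)
  pt <- build_pair_table(m, sites$pred, sites$coords)
  list(model = fit_gdm(pt, predictors = "temp_mean"), grid = g)
}

test_that("transformed surfaces hit 0 at the minimum and the summed
           coefficients at the maximum", {
  mg <- mk_model_on_grid()
  surf <- transform_grid(mg$model, list(temp_mean = mg$grid))$temp_mean
  imp <- unname(gdm_importance(mg$model)["temp_mean"])
  expect_equal(min(surf$values), 0, tolerance = 1e-9)
  expect_equal(max(surf$values), imp, tolerance = 1e-6)
  # mid-range cells match direct basis evaluation
  x <- mg$grid$values[7, 4]
  expect_equal(surf$values[7, 4],
               as.numeric(eval_ispline(mg$model$bases$temp_mean, x) %*%
                            mg$model$coef[, "temp_mean"]),
               tolerance = 1e-10)
  # monotone along the climate variable
  o <- order(as.vector(mg$grid$values))
  expect_true(all(diff(as.vector(surf$values)[o]) >= -1e-12))
  expect_error(transform_grid(mg$model, list()), "no grid")
})

test_that("single-surface composition maps put everything on the R channel", {
  mg <- mk_model_on_grid()
  surf <- transform_grid(mg$model, list(temp_mean = mg$grid))
  map <- pca_rgb(surf)
  r <- map$rgb[, , 1]
  expect_true(all(map$rgb[, , 2] == 0) && all(map$rgb[, , 3] == 0))
  expect_equal(min(r), 0)
  expect_equal(max(r), 255)
  # R channel is a min-max rescale of the surface up to PC sign
  v <- as.vector(surf$temp_mean$values)
  expect_equal(abs(cor(as.vector(r), v)), 1, tolerance = 1e-9)
})

test_that("perfectly correlated surfaces collapse onto one component and
           PCA reconstructs its input", {
  mg <- mk_model_on_grid()
  surf <- transform_grid(mg$model, list(temp_mean = mg$grid))$temp_mean
  s2 <- surf; s2$values <- 2 * surf$values + 1; s2$name <- "copy"
  map <- pca_rgb(list(a = surf, b = s2))
  expect_lt(map$sdev[2]^2 / sum(map$sdev^2), 1e-10)
  # orthogonality: scores %*% t(rotation) reproduces the centred input
  M <- cbind(as.vector(surf$values), as.vector(s2$values))
  Mc <- scale(M, center = TRUE, scale = FALSE)
  rec <- map$pcs[, 1:2] %*% t(map$loadings)
  expect_equal(unname(rec), unname(Mc), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("Procrustes residuals vanish under similarity transforms and
           match a brute-force optimiser on 3-point toys", {
  mk <- function(p) structure(list(pcs = p, cell_ok = rep(TRUE, nrow(p)),
                                   template = NULL),
                              class = "composition_map")
  X <- withr::with_seed(8, matrix(rnorm(24), 8, 3))
  pr0 <- procrustes_residuals(mk(X), mk(X))
  expect_equal(max(pr0$residuals), 0, tolerance = 1e-12)
  th <- 30 * pi / 180
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Y <- 2 * X %*% Rz + matrix(rep(c(3, -1, 2), each = 8), 8)
  pr <- procrustes_residuals(mk(X), mk(Y))
  expect_lt(max(pr$residuals), 1e-8)
  # 3-point planar toys vs brute-force search over angle/scale/translation
  for (s in 1:3) {
    withr::with_seed(50 + s, {
      A <- cbind(matrix(rnorm(6), 3, 2), 0)
      B <- cbind(matrix(rnorm(6), 3, 2), 0)
    })
    pr <- procrustes_residuals(mk(A), mk(B))
    obj <- function(par) {
      th <- par[1]; sc <- exp(par[2]); tx <- par[3]; ty <- par[4]
      Rz2 <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
      fit <- sc * B[, 1:2] %*% Rz2 + matrix(rep(c(tx, ty), each = 3), 3)
      sum((A[, 1:2] - fit)^2)
    }
    best <- Inf
    for (th0 in seq(0, 2 * pi, length.out = 13))
      best <- min(best, optim(c(th0, 0, 0, 0), obj,
                              control = list(reltol = 1e-14,
                                             maxit = 5000))$value)
    # allow reflections in the brute force too: flip one axis of B
    objr <- function(par) {
      Bf <- B[, 1:2] %*% diag(c(1, -1))
      th <- par[1]; sc <- exp(par[2]); tx <- par[3]; ty <- par[4]
      Rz2 <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
      fit <- sc * Bf %*% Rz2 + matrix(rep(c(tx, ty), each = 3), 3)
      sum((A[, 1:2] - fit)^2)
    }
    for (th0 in seq(0, 2 * pi, length.out = 13))
      best <- min(best, optim(c(th0, 0, 0, 0), objr,
                              control = list(reltol = 1e-14,
                                             maxit = 5000))$value)
    expect_equal(pr$rss, best, tolerance = 1e-6)
  }
})

test_that("Procrustes agrees with an established implementation", {
  mk <- function(p) structure(list(pcs = p, cell_ok = rep(TRUE, nrow(p)),
                                   template = NULL),
                              class = "composition_map")
  withr::with_seed(9, {
    X <- matrix(rnorm(45), 15, 3)
    Y <- matrix(rnorm(45), 15, 3)
  })
  pr <- procrustes_residuals(mk(X), mk(Y))
  v <- vegan::procrustes(X, Y, symmetric = FALSE)
  expect_equal(unname(pr$residuals),
               unname(sqrt(rowSums((v$X - v$Yrot)^2))), tolerance = 1e-8)
})

test_that("cross-species residual scaling pools the min and max", {
  sc <- scale_residuals_across(c(0, 1, 2), c(3, 4))
  expect_equal(sc$a, c(0, 0.25, 0.5))
  expect_equal(sc$b, c(0.75, 1))
  # ranks preserved within each set
  withr::with_seed(10, {
    a <- runif(20); b <- runif(10) + 0.5
  })
  sc2 <- scale_residuals_across(a, b)
  expect_identical(order(sc2$a), order(a))
  expect_error(scale_residuals_across(rep(1, 3), rep(1, 2)), "degenerate")
})
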