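# PCA-outlier scan, latent-factor ridge scan, scree rule, q-values.

test_that("scree elbow rule follows the 5% gap criterion", {
  expect_equal(choose_k_scree(c(10, 1, 0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3,
                                0.2)), 1)
  expect_equal(choose_k_scree(c(10, 9, 1, 0.9, 0.8, 0.7, 0.6, 0.5, 0.4,
                                0.3)), 2)
  expect_warning(k <- choose_k_scree(rep(2, 10)), "flat")
  expect_equal(k, 1)
})

test_that("Storey q-values are monotone, bounded and conservative on nulls", {
  set.seed(4)
  p <- runif(2000)
  q <- storey_qvalue(p)
  expect_true(all(q >= 0 & q <= 1))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_lte(sum(q < 0.05), 2)
  # strong signals get small q
  p2 <- c(rep(1e-10, 10), runif(990))
  expect_true(all(storey_qvalue(p2)[1:10] < 1e-6))
})

test_that("duplicated loci get identical PCA-scan statistics", {
  sm <- small_sim(seed = 9, n_neutral = 80, n_adaptive = 0,
                  missing_rate = 0)
  g <- sm$genotypes
  dup <- subset_idx <- c(seq_len(ncol(g$counts)), 1L)
  g2 <- genotype_matrix(g$counts[, dup],
                        g$samples,
                        data.frame(id = c(g$loci$id, "L_dup"),
                                   fragment_id = c(g$loci$fragment_id, "FX"),
                                   reproducibility = 1))
  s <- pca_outlier_scan(g2, K = 2)
  first <- s$loci[1, ]
  last <- s$loci[nrow(s$loci), ]
  expect_equal(last$statistic, first$statistic, tolerance = 1e-12)
  expect_equal(last$p, first$p, tolerance = 1e-12)
})

test_that("PCA scan is calibrated under no structure and flags the planted
           differentiated locus under structure", {
  # null: no structure at all -> lambda near 1, almost no discoveries
  frac <- lam <- numeric(3)
  for (s in 1:3) {
    sm <- small_sim(seed = 20 + s, n_pops = 8, n_ind = 15, n_neutral = 800,
                    n_adaptive = 0, fst = 1e-13, missing_rate = 0)
    sc <- pca_outlier_scan(sm$genotypes, K = 1)
    frac[s] <- mean(sc$loci$significant)
    lam[s] <- sc$params$lambda
  }
  expect_true(all(lam > 0.8 & lam < 1.2))
  expect_true(all(frac <= 0.01))
  # two diverged pops; one locus fixed differently reaches the max D2
  sm <- small_sim(seed = 31, n_pops = 2, n_ind = 20, n_neutral = 150,
                  n_adaptive = 0, fst = 0.05, missing_rate = 0)
  g <- sm$genotypes
  g$counts[, 1] <- ifelse(g$samples$population ==
                            g$samples$population[1], 0L, 2L)
  sc <- pca_outlier_scan(g, K = 1)
  expect_equal(which.max(sc$loci$statistic), 1L)
})

test_that("robust Mahalanobis agrees with explicit-inverse brute force", {
  sm <- small_sim(seed = 10, n_neutral = 50, n_adaptive = 0,
                  missing_rate = 0)
  g <- sm$genotypes
  sc <- pca_outlier_scan(g, K = 3)
  # brute force: rebuild z the same way, then D2 via explicit solve()
  Y <- g$counts
  p_hat <- colMeans(Y) / 2
  keep <- pmin(p_hat, 1 - p_hat) >= 0.05 & apply(Y, 2, var) > 0
  Ys <- scale(Y[, keep], center = 2 * p_hat[keep],
              scale = sqrt(2 * p_hat[keep] * (1 - p_hat[keep])))
  n <- nrow(Ys)
  sv <- svd(Ys)
  scores <- sv$u[, 1:3] * sqrt(n - 1)
  z <- t(crossprod(scores, Ys) / (n - 1))
  ctr <- apply(z, 2, median)
  S <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    S[i, j] <- if (i == j) mad(z[, i])^2 else
      (mad(z[, i] + z[, j])^2 - mad(z[, i] - z[, j])^2) / 4
  }
  e <- eigen(S, symmetric = TRUE)
  S <- e$vectors %*% (pmax(e$values, max(e$values) * 1e-8) * t(e$vectors))
  d <- sweep(z, 2, ctr)
  D2 <- rowSums(d * t(solve(S, t(d))))
  expect_equal(unname(sc$loci$statistic[keep]), unname(D2),
               tolerance = 1e-8)
})

test_that("iterative SVD imputation reconstructs low-rank structure", {
  set.seed(11)
  u <- runif(60, 0.5, 1); v <- runif(150, 0, 2)
  M <- outer(u, v)  # exactly rank 1, already inside [0, 2]
  holes <- sample(length(M), length(M) * 0.1)
  Mh <- M; Mh[holes] <- NA
  out <- lfmm_impute(Mh, K = 1)
  expect_lt(sqrt(mean((out[holes] - M[holes])^2)), 0.1)
  # complete input is returned untouched; imputation is deterministic
  expect_identical(lfmm_impute(M, K = 2), M)
  expect_identical(out, lfmm_impute(Mh, K = 1))
  Mh[, 1] <- NA
  expect_error(lfmm_impute(Mh, K = 1), "entirely missing")
})

test_that("ridge scan with K = 0 matches the closed-form OLS t-statistic", {
  sm <- small_sim(seed = 12, n_neutral = 40, n_adaptive = 0,
                  missing_rate = 0)
  g <- sm$genotypes
  env <- sm$clim[match(g$samples$id, sm$clim$sample_id), "temp_mean",
                 drop = FALSE]
  sc <- lfmm_ridge_scan(g, env, K = 0)
  x <- scale(env[[1]])[, 1]
  for (j in c(1, 7, 20)) {
    fit <- summary(lm(g$counts[, j] ~ x))
    expect_equal(abs(sc$detail$z[j, 1]),
                 abs(fit$coefficients["x", "t value"]), tolerance = 1e-8)
  }
})

test_that("duplicated environmental variables give identical z-scores", {
  sm <- small_sim(seed = 13, n_neutral = 60, n_adaptive = 0,
                  missing_rate = 0)
  g <- sm$genotypes
  env <- sm$clim[match(g$samples$id, sm$clim$sample_id),
                 c("temp_mean", "temp_mean")]
  names(env) <- c("e1", "e2")
  sc <- lfmm_ridge_scan(g, env, K = 2)
  expect_equal(sc$detail$z[, "e1"], sc$detail$z[, "e2"], tolerance = 1e-10)
  expect_error(lfmm_ridge_scan(g, data.frame(e = rep(1, nrow(g$counts))),
                               K = 1), "constant")
})

test_that("ridge scan is calibrated on nulls and detects a planted cline", {
  hits <- 0; lam_ok <- 0; null_frac <- numeric(0)
  for (s in 1:5) {
    sm <- small_sim(seed = 40 + s, n_pops = 10, n_ind = 15, n_neutral = 500,
                    n_adaptive = 1, fst = 0.05, beta = 3,
                    drivers = "temp_mean", missing_rate = 0)
    g <- sm$genotypes
    env <- sm$clim[match(g$samples$id, sm$clim$sample_id), "temp_mean",
                   drop = FALSE]
    sc <- lfmm_ridge_scan(g, env, K = 2)
    planted <- sm$truth$adaptive_ids
    if (all(sc$loci$significant[match(planted, sc$loci$locus_id)]))
      hits <- hits + 1
    null_frac <- c(null_frac,
                   mean(sc$loci$significant[!sc$loci$locus_id %in% planted]))
  }
  expect_gte(hits, 4)
  expect_lte(mean(null_frac), 0.02)
})
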