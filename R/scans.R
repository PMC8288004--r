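# Genome scans: (1) PCA-outlier population-differentiation test with a
# robust Mahalanobis statistic, genomic-inflation calibration and Storey
# q-values; (2) latent-factor ridge environment association with per-variable
# inflation calibration and Benjamini-Hochberg control. The Bayesian
# allele-frequency-covariance scan lives in baypass.R.

scan_result <- function(method, tab, params) {
  structure(list(method = method, loci = tab, params = params),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result> %s: %d loci, %d significant\n", x$method,
              nrow(x$loci), sum(x$loci$significant, na.rm = TRUE)))
  invisible(x)
}

#' Write a scan result as CSV
#' @param x A `scan_result`.
#' @param path Output path.
#' @export
write_scan_result <- function(x, path) {
  df <- x$loci
  df$method <- x$method
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

significant_ids <- function(x) x$loci$locus_id[x$loci$significant %in% TRUE]

#' Storey q-values
#'
#' The proportion of true nulls is estimated as
#' `pi0 = min(1, mean(p > lambda) / (1 - lambda))` and q-values are the
#' usual step-up cumulative minima of `pi0 * m * p_(i) / i`.
#'
#' @param p P-values.
#' @param lambda Tuning point for the `pi0` estimate (default 0.5).
#' @return Q-values in the order of `p`.
#' @export
storey_qvalue <- function(p, lambda = 0.5) {
  ok <- !is.na(p)
  m <- sum(ok)
  q <- rep(NA_real_, length(p))
  if (m == 0) return(q)
  pi0 <- min(1, mean(p[ok] > lambda) / (1 - lambda))
  pi0 <- max(pi0, 1 / m)  # guard against 0 when all p are tiny
  o <- order(p[ok])
  ranked <- pi0 * m * p[ok][o] / seq_len(m)
  qv <- rev(cummin(rev(ranked)))
  q[ok][o] <- pmin(qv, 1)
  q
}

#' Choose the number of components from a scree plot
#'
#' Operationalizes the elbow rule: K is the largest index whose eigenvalue
#' drop `(lambda_K - lambda_{K+1})` exceeds 5% of the spread
#' `lambda_1 - lambda_{k_max}`, with minimum 1.
#'
#' @param eigenvalues Nonincreasing positive eigenvalues (length >= 2).
#' @param k_max Largest K considered (default 10).
#' @return Integer K.
#' @export
choose_k_scree <- function(eigenvalues, k_max = 10) {
  ev <- eigenvalues
  assert_that(length(ev) >= 2, "need at least two eigenvalues")
  assert_that(all(diff(ev) <= 1e-8), "eigenvalues must be nonincreasing")
  k_top <- min(k_max, length(ev))
  spread <- ev[1] - ev[k_top]
  if (spread <= 0) {
    warning("flat eigenvalue spectrum; K = 1")
    return(1L)
  }
  gaps <- (ev[-length(ev)] - ev[-1])[seq_len(k_top - 1)] / spread
  k <- which(gaps > 0.05)
  if (length(k) == 0) 1L else max(k)
}

# mean-impute missing calls per locus
impute_mean <- function(counts) {
  mu <- colMeans(counts, na.rm = TRUE)
  idx <- which(is.na(counts))
  if (length(idx) > 0)
    counts[idx] <- mu[(idx - 1) %/% nrow(counts) + 1]
  counts
}

# Pairwise robust scatter (Gnanadesikan-Kettenring): covariances from MADs of
# sums and differences, eigenvalue-clamped to positive definite. Deterministic.
robust_scatter <- function(z) {
  K <- ncol(z)
  ctr <- apply(z, 2, median)
  if (K == 1) {
    s <- mad(z[, 1])^2
    return(list(center = ctr, cov = matrix(max(s, 1e-12), 1, 1)))
  }
  S <- matrix(0, K, K)
  for (i in seq_len(K)) {
    S[i, i] <- mad(z[, i])^2
    for (j in seq_len(K)) if (j > i) {
      s <- (mad(z[, i] + z[, j])^2 - mad(z[, i] - z[, j])^2) / 4
      S[i, j] <- S[j, i] <- s
    }
  }
  e <- eigen(S, symmetric = TRUE)
  ev <- pmax(e$values, max(e$values) * 1e-8)
  list(center = ctr, cov = e$vectors %*% (ev * t(e$vectors)))
}

#' PCA-outlier scan for population differentiation
#'
#' Genotypes are mean-imputed, centred and scaled by the binomial standard
#' deviation `sqrt(2 p (1 - p))`; the top-K principal components are taken
#' from the SVD; each locus gets the K-vector of regression slopes of its
#' scaled genotypes on the unit-variance component scores; the squared
#' robust Mahalanobis distance of those vectors (median/MAD pairwise robust
#' scatter) is calibrated by the genomic inflation factor
#' `lambda = median(D^2) / median(chi^2_K)` and converted to chi-squared
#' p-values, with Storey q-values for FDR control.
#'
#' Loci below the MAF threshold (or with zero variance) are excluded from
#' the test and reported with `NA` statistics.
#'
#' @param g A [genotype_matrix].
#' @param K Number of principal components (>= 1); `NULL` chooses K from the
#'   scree of the genotype covariance spectrum via [choose_k_scree()].
#' @param fdr Q-value threshold for calling outliers (default 0.05).
#' @param min_maf MAF threshold; loci with MAF >= `min_maf` are tested.
#' @return A `scan_result` with per-locus `statistic` (D^2), `p`, `q`,
#'   `significant`, and `K`, `lambda` in `$params`.
#' @export
pca_outlier_scan <- function(g, K = NULL, fdr = 0.05, min_maf = 0.05) {
  Y <- impute_mean(g$counts)
  p_hat <- colMeans(Y) / 2
  maf <- pmin(p_hat, 1 - p_hat)
  testable <- maf >= min_maf & apply(Y, 2, var) > 0
  if (sum(!testable) > 0)
    message(sum(!testable), " loci excluded from PCA scan (MAF/zero variance)")
  Ys <- scale(Y[, testable, drop = FALSE],
              center = 2 * p_hat[testable],
              scale = sqrt(2 * p_hat[testable] * (1 - p_hat[testable])))
  n <- nrow(Ys)
  sv <- svd(Ys)
  if (is.null(K)) {
    ev <- sv$d^2 / (n - 1)
    K <- choose_k_scree(ev, k_max = min(10, length(ev)))
  }
  assert_that(K >= 1, "K must be >= 1")
  if (K >= min(dim(Ys))) stopf("K must be smaller than min(individuals, loci)")
  # unit-variance scores; slopes of each scaled locus on the scores
  scores <- sv$u[, seq_len(K), drop = FALSE] * sqrt(n - 1)
  z <- crossprod(scores, Ys) / (n - 1)         # K x loci slope matrix
  z <- t(z)
  rs <- robust_scatter(z)
  d <- sweep(z, 2, rs$center)
  D2 <- rowSums((d %*% solve(rs$cov)) * d)
  lambda <- median(D2) / qchisq(0.5, df = K)
  p <- pchisq(D2 / lambda, df = K, lower.tail = FALSE)
  q <- storey_qvalue(p)
  tab <- data.frame(locus_id = g$loci$id, statistic = NA_real_, p = NA_real_,
                    q = NA_real_, db = NA_real_, significant = FALSE,
                    stringsAsFactors = FALSE)
  tab$statistic[testable] <- D2
  tab$p[testable] <- p
  tab$q[testable] <- q
  tab$significant[testable] <- q < fdr
  scan_result("pca_outlier", tab,
              list(K = K, lambda = lambda, fdr = fdr, min_maf = min_maf))
}

#' Impute missing genotypes by iterative rank-K SVD reconstruction
#'
#' Missing cells start at locus means; truncated SVD reconstruction and
#' refill alternate until the RMS change over missing cells drops below
#' `tol` (or `maxit` iterations). The completed matrix is clamped into
#' `[0, 2]`.
#'
#' @param g A [genotype_matrix] (or plain matrix).
#' @param K Reconstruction rank (>= 1).
#' @param tol,maxit Convergence controls.
#' @return A complete numeric matrix (individuals x loci).
#' @export
lfmm_impute <- function(g, K, tol = 1e-4, maxit = 50) {
  Y <- if (inherits(g, "genotype_matrix")) g$counts else as.matrix(g)
  assert_that(K >= 1, "K must be >= 1")
  if (any(colSums(!is.na(Y)) == 0)) stopf("locus entirely missing")
  idx <- which(is.na(Y))
  if (length(idx) == 0) return(Y)
  X <- impute_mean(Y)
  K <- min(K, min(dim(Y)) - 1)
  for (it in seq_len(maxit)) {
    sv <- svd(X, nu = K, nv = K)
    rec <- sv$u %*% (sv$d[seq_len(K)] * t(sv$v))
    delta <- sqrt(mean((rec[idx] - X[idx])^2))
    X[idx] <- rec[idx]
    if (delta < tol) break
  }
  pmin(pmax(X, 0), 2)
}

#' Latent-factor ridge environment association scan
#'
#' For each climate variable (scaled to unit standard deviation): the
#' variable is regressed out of the centred genotype matrix, K latent
#' factors are estimated from the truncated SVD of the residuals, and each
#' locus is refit by ordinary least squares on `[variable, factors]`. The
#' squared z-scores of the variable effect are calibrated by the genomic
#' inflation factor `lambda = median(z^2) / median(chi^2_1)` and converted
#' to chi-squared p-values, with per-variable Benjamini-Hochberg control.
#' A locus is significant if any variable reaches `q < fdr`.
#'
#' @param g A [genotype_matrix] or complete matrix (impute first with
#'   [lfmm_impute()] if needed).
#' @param env Per-individual environment data frame or matrix (columns =
#'   variables), rows aligned with the genotype rows.
#' @param K Number of latent factors (0 degenerates to simple per-locus
#'   regression).
#' @param fdr Per-variable BH threshold (default 0.05).
#' @return A `scan_result`; `$detail` holds per-variable z, p, q matrices
#'   and `$params$lambda` the per-variable inflation factors.
#' @export
lfmm_ridge_scan <- function(g, env, K, fdr = 0.05) {
  Y <- if (inherits(g, "genotype_matrix")) g$counts else as.matrix(g)
  if (anyNA(Y)) stopf("genotype matrix must be complete; run lfmm_impute first")
  env <- as.matrix(env)
  n <- nrow(Y)
  assert_that(nrow(env) == n, "env rows must match genotype rows")
  assert_that(K >= 0, "K must be >= 0")
  if (K >= n) stopf("K must be smaller than the number of individuals")
  sds <- apply(env, 2, sd)
  if (any(sds == 0)) stopf("constant environmental variable: %s",
                           paste(colnames(env)[sds == 0], collapse = ", "))
  vars <- colnames(env) %||% paste0("V", seq_len(ncol(env)))
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  zmat <- pmat <- qmat <- matrix(NA_real_, ncol(Y), length(vars),
                                 dimnames = list(colnames(Y), vars))
  lambdas <- setNames(numeric(length(vars)), vars)
  for (j in seq_along(vars)) {
    x <- scale(env[, j], center = TRUE, scale = TRUE)[, 1]
    if (K > 0) {
      bx <- crossprod(x, Yc) / sum(x^2)
      R <- Yc - tcrossprod(x, as.vector(bx))
      sv <- svd(R, nu = K, nv = 0)
      D <- cbind(1, x, sv$u[, seq_len(K), drop = FALSE])
    } else {
      D <- cbind(1, x)
    }
    qr_d <- qr(D)
    coefs <- qr.coef(qr_d, Yc)
    res <- Yc - D %*% coefs
    dfres <- n - ncol(D)
    sigma2 <- colSums(res^2) / dfres
    xtx_inv <- chol2inv(qr.R(qr_d))
    se <- sqrt(sigma2 * xtx_inv[2, 2])
    zj <- coefs[2, ] / se
    zj[se == 0] <- 0
    lam <- median(zj^2) / qchisq(0.5, df = 1)
    pj <- pchisq(zj^2 / lam, df = 1, lower.tail = FALSE)
    zmat[, j] <- zj
    pmat[, j] <- pj
    qmat[, j] <- p.adjust(pj, method = "BH")
    lambdas[j] <- lam
  }
  best <- apply(qmat, 1, min)
  locus_ids <- if (inherits(g, "genotype_matrix")) g$loci$id else
    colnames(Y) %||% sprintf("L%05d", seq_len(ncol(Y)))
  tab <- data.frame(locus_id = locus_ids,
                    statistic = apply(zmat^2, 1, max),
                    p = apply(pmat, 1, min), q = best, db = NA_real_,
                    significant = best < fdr, stringsAsFactors = FALSE)
  out <- scan_result("lfmm_ridge", tab,
                     list(K = K, lambda = lambdas, fdr = fdr))
  out$detail <- list(z = zmat, p = pmat, q = qmat)
  out
}
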