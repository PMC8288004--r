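# Weir & Cockerham (1984) variance-components estimator of FST (theta),
# global and pairwise, plus unit-interval scaling of the pairwise matrix
# for use as a dissimilarity response.

# Per-population, per-locus summaries: sample sizes (individuals), allele
# frequencies and observed heterozygosity.
pop_locus_summaries <- function(g) {
  pops <- sort(unique(g$samples$population))
  L <- ncol(g$counts)
  n <- p <- h <- matrix(0, length(pops), L,
                        dimnames = list(pops, colnames(g$counts)))
  for (i in seq_along(pops)) {
    sub <- g$counts[g$samples$population == pops[i], , drop = FALSE]
    called <- colSums(!is.na(sub))
    n[i, ] <- called
    p[i, ] <- ifelse(called > 0, colSums(sub, na.rm = TRUE) / (2 * called), NA)
    h[i, ] <- ifelse(called > 0, colSums(sub == 1, na.rm = TRUE) / called, NA)
  }
  list(n = n, p = p, h = h, pops = pops)
}

# Variance components a (among populations), b (among individuals within),
# c (within individuals) per locus, over the populations in `rows`.
wc_components <- function(sm, rows) {
  n <- sm$n[rows, , drop = FALSE]
  p <- sm$p[rows, , drop = FALSE]
  h <- sm$h[rows, , drop = FALSE]
  use <- colSums(n > 0) >= 2
  a <- b <- cc <- numeric(ncol(n))
  if (!any(use)) return(list(a = a, b = b, c = cc))
  n <- n[, use, drop = FALSE]; p <- p[, use, drop = FALSE]
  h <- h[, use, drop = FALSE]
  present <- n > 0
  r <- colSums(present)
  nbar <- colSums(n) / r
  nc <- (colSums(n) - colSums(n^2) / colSums(n)) / (r - 1)
  pbar <- colSums(n * p, na.rm = TRUE) / (r * nbar)
  s2 <- colSums(n * (p - rep(pbar, each = nrow(p)))^2, na.rm = TRUE) /
    ((r - 1) * nbar)
  hbar <- colSums(n * h, na.rm = TRUE) / (r * nbar)
  av <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  bv <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cv <- hbar / 2
  mono <- pbar <= 0 | pbar >= 1  # monomorphic: zero components
  av[mono] <- bv[mono] <- cv[mono] <- 0
  a[use] <- av; b[use] <- bv; cc[use] <- cv
  list(a = a, b = b, c = cc)
}

#' Multilocus Weir-Cockerham theta
#'
#' The 1984 variance-components estimator: per-locus components `a` (among
#' populations), `b` (among individuals within populations) and `c` (within
#' individuals), combined across loci as `theta = sum(a) / sum(a + b + c)`.
#' Loci monomorphic across the involved populations contribute zero
#' components.
#'
#' @param g A [genotype_matrix].
#' @param locus_subset Locus ids (or indices) to use; default all.
#' @param pops Populations to include; default all (>= 2 required).
#' @return Multilocus theta (scalar).
#' @export
wc_theta <- function(g, locus_subset = NULL, pops = NULL) {
  if (!is.null(locus_subset)) {
    idx <- if (is.character(locus_subset)) match(locus_subset, g$loci$id)
    else locus_subset
    g <- subset_genotypes(g, loci = idx)
  }
  sm <- pop_locus_summaries(g)
  rows <- if (is.null(pops)) seq_along(sm$pops) else match(pops, sm$pops)
  assert_that(length(rows) >= 2, "need at least two populations")
  if (any(rowSums(sm$n[rows, , drop = FALSE]) == 0))
    stopf("a population has no data at every locus")
  comp <- wc_components(sm, rows)
  denom <- sum(comp$a + comp$b + comp$c)
  if (denom == 0) return(0)
  sum(comp$a) / denom
}

#' Global and pairwise Weir-Cockerham theta matrix
#'
#' @param g A [genotype_matrix].
#' @param locus_subset Locus ids or indices; default all.
#' @return An `fst_matrix`: `theta` (symmetric pairwise matrix, zero
#'   diagonal) and `global` (multilocus theta over all populations).
#' @export
pairwise_fst <- function(g, locus_subset = NULL) {
  if (!is.null(locus_subset)) {
    idx <- if (is.character(locus_subset)) match(locus_subset, g$loci$id)
    else locus_subset
    g <- subset_genotypes(g, loci = idx)
  }
  sm <- pop_locus_summaries(g)
  pops <- sm$pops
  assert_that(length(pops) >= 2, "need at least two populations")
  th <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_along(pops)) if (j > i) {
    comp <- wc_components(sm, c(i, j))
    denom <- sum(comp$a + comp$b + comp$c)
    th[i, j] <- th[j, i] <- if (denom == 0) 0 else sum(comp$a) / denom
  }
  compg <- wc_components(sm, seq_along(pops))
  denomg <- sum(compg$a + compg$b + compg$c)
  structure(list(theta = th,
                 global = if (denomg == 0) 0 else sum(compg$a) / denomg),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat(sprintf("<fst_matrix> %d populations, global theta = %.4f\n",
              nrow(x$theta), x$global))
  invisible(x)
}

#' Scale a pairwise FST matrix into the unit interval
#'
#' Off-diagonal entries are min-max scaled (`(x - min) / (max - min)`), the
#' default, or divided by the maximum (`method = "divmax"`). The diagonal
#' stays zero.
#'
#' @param fst An `fst_matrix` or square symmetric matrix.
#' @param method `"minmax"` (default) or `"divmax"`.
#' @return Scaled matrix in `[0, 1]`.
#' @export
scale_unit <- function(fst, method = c("minmax", "divmax")) {
  method <- match.arg(method)
  m <- if (inherits(fst, "fst_matrix")) fst$theta else as.matrix(fst)
  off <- m[upper.tri(m)]
  assert_that(length(unique(off)) >= 2,
              "all off-diagonal values equal: degenerate response")
  out <- m
  if (method == "minmax") {
    rng <- range(off)
    out[upper.tri(out) | lower.tri(out)] <-
      (m[upper.tri(m) | lower.tri(m)] - rng[1]) / diff(rng)
  } else {
    out[upper.tri(out) | lower.tri(out)] <-
      m[upper.tri(m) | lower.tri(m)] / max(off)
  }
  diag(out) <- 0
  out
}

#' Write an FST matrix as CSV
#' @param x An `fst_matrix`.
#' @param path Output path.
#' @export
write_fst_matrix <- function(x, path) {
  df <- data.frame(population = rownames(x$theta), x$theta,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
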