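# Shared fixtures: small in-code data sets and desk-scale runtime settings.

# MCMC settings for desk-scale runs (shortened chains; see methods vignette)
desk_bp <- function() {
  bp_settings(n_iter = 2500, burnin = 1250, npilot = 6, pilotlength = 250,
              thin = 5, n_chains = 2)
}

# even shorter chains for module-level unit tests
tiny_bp <- function(n_chains = 2) {
  bp_settings(n_iter = 1200, burnin = 600, npilot = 4, pilotlength = 150,
              thin = 4, n_chains = n_chains)
}

# small landscape + one-species simulation used across module tests
small_sim <- function(seed = 1, n_pops = 8, n_ind = 10, n_neutral = 300,
                      n_adaptive = 5, fst = 0.1, beta = 3,
                      drivers = "temp_mean", missing_rate = 0.012) {
  setup <- default_pair_setup(seed)
  cfg <- sim_config(n_pops = n_pops, n_ind_per_pop = c(n_ind, n_ind),
                    n_neutral = n_neutral, n_adaptive = n_adaptive,
                    drivers = drivers, effect_beta = beta, fst_target = fst,
                    missing_rate = missing_rate, seed = seed + 1000)
  sites <- sample_sites(setup$grids, n_pops, c(n_ind, n_ind), seed = seed)
  clim <- extract_at_points(setup$grids, sites)
  sim <- simulate_genotypes(sites, clim, cfg)
  list(grids = setup$grids, sites = sites, clim = clim,
       genotypes = sim$genotypes, truth = sim$truth, config = cfg)
}

# tiny hand-built genotype matrix
toy_genotypes <- function() {
  counts <- rbind(c(0L, 1L, 2L, 1L),
                  c(1L, 1L, 0L, NA),
                  c(2L, 0L, 1L, 0L),
                  c(0L, 2L, 2L, 1L))
  samples <- data.frame(id = paste0("S", 1:4),
                        population = c("A", "A", "B", "B"),
                        lon = c(116.1, 116.2, 118.4, 118.5),
                        lat = c(-27.2, -27.3, -29.1, -29.2),
                        stringsAsFactors = FALSE)
  loci <- data.frame(id = paste0("L", 1:4),
                     fragment_id = c("F1", "F1", "F2", "F3"),
                     reproducibility = c(1, 0.99, 1, 1),
                     stringsAsFactors = FALSE)
  genotype_matrix(counts, samples, loci)
}

# independent brute-force Weir-Cockerham (1984) theta, written directly from
# the variance-component formulas (per-locus loops, no shared code)
brute_wc_theta <- function(counts, pops) {
  pop_levels <- unique(pops)
  num <- den <- 0
  for (l in seq_len(ncol(counts))) {
    gl <- counts[, l]
    keep <- !is.na(gl)
    n_i <- p_i <- h_i <- numeric(0)
    for (pp in pop_levels) {
      gg <- gl[keep & pops == pp]
      if (length(gg) == 0) next
      n_i <- c(n_i, length(gg))
      p_i <- c(p_i, mean(gg) / 2)
      h_i <- c(h_i, mean(gg == 1))
    }
    r <- length(n_i)
    if (r < 2) next
    nbar <- mean(n_i)
    nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
    pbar <- sum(n_i * p_i) / sum(n_i)
    if (pbar <= 0 || pbar >= 1) next
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / sum(n_i)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}
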