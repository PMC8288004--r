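# Synthetic paired host/parasite data sets with known climatic drivers.
# Neutral structure follows the Balding-Nichols beta model with a single
# differentiation parameter F per species; adaptive loci follow logistic
# allele-frequency clines in a designated climate variable. DArTseq-like
# artefacts (missingness, fragment multiplicity, reproducibility scores)
# are layered on top so the QC filters have something to do.

#' Simulation configuration
#'
#' @param n_pops Number of populations (>= 2).
#' @param n_ind_per_pop Integer range `c(min, max)` of individuals per
#'   population; counts are drawn uniformly in the range.
#' @param n_neutral,n_adaptive Numbers of neutral and adaptive loci
#'   (`n_adaptive <= n_neutral`).
#' @param drivers Character vector of climate-variable names driving the
#'   adaptive loci (recycled across adaptive loci).
#' @param effect_beta Logistic slope per adaptive locus, in units of
#'   standardized climate (recycled).
#' @param fst_target Balding-Nichols differentiation parameter F in `[0, 1)`.
#' @param missing_rate Fraction of genotype calls set missing, in `[0, 0.5]`.
#' @param snps_per_fragment Named probabilities over fragment sizes
#'   `{1, 2, 3}`.
#' @param repro_score_range Interval for reproducibility scores.
#' @param low_repro_frac Fraction of loci drawn below 0.98 to exercise the
#'   reproducibility filter.
#' @param seed Integer seed governing all draws for this species.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_pops = 10, n_ind_per_pop = c(10, 16),
                       n_neutral = 2000, n_adaptive = 10,
                       drivers = "temp_mean", effect_beta = 3,
                       fst_target = 0.1, missing_rate = 0.012,
                       snps_per_fragment = c(`1` = 0.6, `2` = 0.3, `3` = 0.1),
                       repro_score_range = c(0.95, 1),
                       low_repro_frac = 0.02, seed = 1) {
  assert_that(n_pops >= 2, "n_pops must be >= 2")
  assert_that(n_adaptive <= n_neutral, "n_adaptive must be <= n_neutral")
  assert_that(fst_target >= 0 && fst_target < 1, "F must be in [0, 1)")
  assert_that(missing_rate >= 0 && missing_rate <= 0.5,
              "missing_rate must be in [0, 0.5]")
  assert_that(abs(sum(snps_per_fragment) - 1) < 1e-8,
              "snps_per_fragment probabilities must sum to 1")
  if (length(n_ind_per_pop) == 1) n_ind_per_pop <- rep(n_ind_per_pop, 2)
  structure(list(n_pops = n_pops, n_ind_per_pop = n_ind_per_pop,
                 n_neutral = n_neutral, n_adaptive = n_adaptive,
                 drivers = drivers, effect_beta = effect_beta,
                 fst_target = fst_target, missing_rate = missing_rate,
                 snps_per_fragment = snps_per_fragment,
                 repro_score_range = repro_score_range,
                 low_repro_frac = low_repro_frac, seed = seed),
            class = "sim_config")
}

#' Place populations and individuals on a climate grid
#'
#' Population centroids are chosen by seeded max-min (farthest point)
#' dispersion over the grid cell centres so sites spread across the whole
#' extent; individuals are jittered around their centroid within bounds.
#'
#' @param grids Named list of [climate_grid]s (a shared landscape).
#' @param n_pops Number of populations (>= 2).
#' @param n_ind_per_pop Integer range `c(min, max)`.
#' @param seed Integer seed.
#' @param jitter Standard deviation of the individual jitter, degrees
#'   (default one cell).
#' @return Data frame with `id`, `population`, `lon`, `lat`.
#' @export
sample_sites <- function(grids, n_pops, n_ind_per_pop = c(10, 16), seed = 1,
                         jitter = NULL) {
  assert_that(n_pops >= 2, "n_pops must be >= 2")
  g <- grids[[1]]
  ctr <- grid_cell_centres(g)
  cells <- expand.grid(lon = ctr$x, lat = ctr$y)
  assert_that(n_pops <= nrow(cells), "n_pops exceeds available cells")
  jitter <- jitter %||% g$cell
  if (length(n_ind_per_pop) == 1) n_ind_per_pop <- rep(n_ind_per_pop, 2)
  ext <- grid_extent(g)
  with_seed(sub_seed(seed, 11), {
    # greedy farthest-point dispersion from a random start
    chosen <- sample.int(nrow(cells), 1)
    d2min <- (cells$lon - cells$lon[chosen])^2 + (cells$lat - cells$lat[chosen])^2
    while (length(chosen) < n_pops) {
      nxt <- which.max(d2min)
      chosen <- c(chosen, nxt)
      d2 <- (cells$lon - cells$lon[nxt])^2 + (cells$lat - cells$lat[nxt])^2
      d2min <- pmin(d2min, d2)
    }
    cent <- cells[chosen, ]
    sizes <- seq(n_ind_per_pop[1], n_ind_per_pop[2])
    n_i <- sizes[sample.int(length(sizes), n_pops, replace = TRUE)]
    pop <- rep(sprintf("P%02d", seq_len(n_pops)), n_i)
    lon <- rep(cent$lon, n_i) + rnorm(sum(n_i), 0, jitter)
    lat <- rep(cent$lat, n_i) + rnorm(sum(n_i), 0, jitter)
    eps <- g$cell * 1e-6
    lon <- pmin(pmax(lon, ext["xmin"]), ext["xmax"] - eps)
    lat <- pmin(pmax(lat, ext["ymin"]), ext["ymax"] - eps)
    data.frame(id = sprintf("%s_I%03d", pop, unlist(lapply(n_i, seq_len))),
               population = pop, lon = unname(lon), lat = unname(lat),
               stringsAsFactors = FALSE)
  })
}

#' Simulate genotypes on a landscape
#'
#' Neutral loci: ancestral frequency `p ~ U(0.1, 0.9)` and population
#' frequencies from the Balding-Nichols beta distribution
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`. Adaptive loci: population frequency
#' `plogis(beta * z)` where `z` is the population-mean driver variable
#' standardized across populations. Genotypes are `Binomial(2, freq)` with
#' missing calls, fragment co-membership, and reproducibility scores layered
#' on afterwards.
#'
#' @param samples Sample table from [sample_sites()].
#' @param climate_table Per-sample climate values from [extract_at_points()].
#' @param config A [sim_config()].
#' @return List with `genotypes` (a [genotype_matrix]) and `truth` (a
#'   `sim_truth` list: `adaptive_ids`, `drivers`, `pop_freq`).
#' @export
simulate_genotypes <- function(samples, climate_table, config) {
  stopifnot(inherits(config, "sim_config"))
  miss <- setdiff(samples$id, climate_table$sample_id)
  if (length(miss) > 0)
    stopf("samples without climate values: %s", paste(miss, collapse = ", "))
  pops <- unique(samples$population)
  P <- length(pops)
  n <- nrow(samples)
  L <- config$n_neutral + config$n_adaptive
  drivers <- rep_len(config$drivers, max(config$n_adaptive, 1))
  betas <- rep_len(config$effect_beta, max(config$n_adaptive, 1))
  bad <- setdiff(drivers[seq_len(config$n_adaptive)], names(climate_table))
  if (length(bad) > 0)
    stopf("drivers not present in climate table: %s", paste(bad, collapse = ", "))
  pop_of <- match(samples$population, pops)

  with_seed(sub_seed(config$seed, 23), {
    # locus layout: adaptive loci at seeded random positions
    adaptive_pos <- if (config$n_adaptive > 0)
      sort(sample.int(L, config$n_adaptive)) else integer(0)
    locus_ids <- sprintf("L%05d", seq_len(L))

    freq <- matrix(0, P, L, dimnames = list(pops, locus_ids))
    FF <- config$fst_target
    neutral_pos <- setdiff(seq_len(L), adaptive_pos)
    p_anc <- runif(length(neutral_pos), 0.1, 0.9)
    if (FF < 1e-12) {
      freq[, neutral_pos] <- matrix(p_anc, P, length(neutral_pos), byrow = TRUE)
    } else {
      a <- p_anc * (1 - FF) / FF
      b <- (1 - p_anc) * (1 - FF) / FF
      freq[, neutral_pos] <- matrix(
        rbeta(P * length(neutral_pos), rep(a, each = P), rep(b, each = P)),
        P, length(neutral_pos))
    }
    # adaptive clines on population-mean standardized drivers
    cm <- climate_table[match(samples$id, climate_table$sample_id), , drop = FALSE]
    for (k in seq_along(adaptive_pos)) {
      v <- drivers[k]
      popmean <- tapply(cm[[v]], samples$population, mean)[pops]
      z <- as.numeric(scale(popmean))
      freq[, adaptive_pos[k]] <- plogis(betas[k] * z)
    }

    geno <- matrix(rbinom(n * L, 2, freq[pop_of, ]), n, L,
                   dimnames = list(samples$id, locus_ids))
    if (config$missing_rate > 0)
      geno[runif(n * L) < config$missing_rate] <- NA_integer_

    # fragments: consecutive blocks with sizes drawn from the multiplicity
    # distribution; scores mostly high with a small low-reproducibility tail
    sizes <- integer(0)
    while (sum(sizes) < L)
      sizes <- c(sizes, sample(as.integer(names(config$snps_per_fragment)), 50,
                               replace = TRUE, prob = config$snps_per_fragment))
    frag <- rep(seq_along(sizes), sizes)[seq_len(L)]
    fragment_id <- sprintf("F%05d", frag)
    lo <- config$repro_score_range[1]
    hi <- config$repro_score_range[2]
    low <- runif(L) < config$low_repro_frac
    repro <- ifelse(low, runif(L, min(lo, 0.9), 0.98),
                    runif(L, max(lo, 0.98), hi))
    g <- genotype_matrix(geno, samples,
                         data.frame(id = locus_ids, fragment_id = fragment_id,
                                    reproducibility = repro,
                                    stringsAsFactors = FALSE))
    truth <- structure(list(adaptive_ids = locus_ids[adaptive_pos],
                            drivers = setNames(drivers[seq_along(adaptive_pos)],
                                               locus_ids[adaptive_pos]),
                            pop_freq = freq), class = "sim_truth")
    list(genotypes = g, truth = truth)
  })
}

#' Default landscape and species configurations for a paired simulation
#'
#' Four climate variables (two temperature, two precipitation) on a 50 x 50
#' grid of 0.1-degree cells; the temperature gradient runs west-east and the
#' precipitation gradient south-north (90 degrees of angular separation).
#' The parasite is strongly differentiated (F = 0.3) with temperature-driven
#' adaptive loci; the host is weakly differentiated (F = 0.08) with
#' precipitation-driven adaptive loci.
#'
#' @param seed Integer seed.
#' @return List with `grids`, `host_config`, `parasite_config`.
#' @export
default_pair_setup <- function(seed = 1) {
  specs <- list(
    list(name = "temp_mean", group = "temperature", direction = 0,
         base = 14, range = 8, noise = 0.6),
    list(name = "temp_seasonality", group = "temperature", direction = 25,
         base = 400, range = 250, noise = 20),
    list(name = "precip_annual", group = "precipitation", direction = 90,
         base = 250, range = 220, noise = 18),
    list(name = "precip_seasonality", group = "precipitation", direction = 115,
         base = 40, range = 35, noise = 3))
  grids <- make_climate_grid(c(116, 121, -31, -26), 0.1, specs,
                             seed = sub_seed(seed, 31))
  host <- sim_config(n_pops = 10, n_ind_per_pop = c(15, 15),
                     n_neutral = 2000, n_adaptive = 10,
                     drivers = "precip_annual", effect_beta = 3,
                     fst_target = 0.08, seed = sub_seed(seed, 41))
  parasite <- sim_config(n_pops = 10, n_ind_per_pop = c(15, 15),
                         n_neutral = 2000, n_adaptive = 10,
                         drivers = "temp_mean", effect_beta = 3,
                         fst_target = 0.30, seed = sub_seed(seed, 43))
  list(grids = grids, host_config = host, parasite_config = parasite)
}

#' Simulate a paired host/parasite data set on a shared landscape
#'
#' Both species share population centroids (the species with fewer
#' populations uses a leading subset, mirroring designs where parasite and
#' host population counts differ by one); individuals, genotypes and
#' artefacts are drawn independently per species. By default the parasite is
#' more differentiated than the host and its adaptive loci track temperature
#' while the host's track precipitation.
#'
#' @param host_config,parasite_config [sim_config()]s; defaults from
#'   [default_pair_setup()].
#' @param grids Shared climate grids; defaults from [default_pair_setup()].
#' @param seed Shared integer seed (drives site placement and defaults).
#' @return List with `host` and `parasite` bundles (each `genotypes`,
#'   `truth`, `samples`, `climate`) plus the shared `grids`.
#' @export
simulate_pair <- function(host_config = NULL, parasite_config = NULL,
                          grids = NULL, seed = 1) {
  setup <- default_pair_setup(seed)
  host_config <- host_config %||% setup$host_config
  parasite_config <- parasite_config %||% setup$parasite_config
  grids <- grids %||% setup$grids
  assert_that(abs(host_config$n_pops - parasite_config$n_pops) <= 1,
              "species population counts may differ by at most 1")
  n_max <- max(host_config$n_pops, parasite_config$n_pops)
  one <- function(cfg, tag, offset) {
    sites <- sample_sites(grids, n_max, cfg$n_ind_per_pop,
                          seed = sub_seed(seed, 7))  # shared centroid stream
    # restrict to this species' population count, then redraw individuals
    keep <- sites$population %in% sprintf("P%02d", seq_len(cfg$n_pops))
    sites <- sites[keep, , drop = FALSE]
    # per-species jitter of individuals: re-jitter with the species seed so
    # the two species share centroids but not individual coordinates
    cent <- aggregate(sites[c("lon", "lat")], list(population = sites$population),
                      mean)
    with_seed(sub_seed(cfg$seed, offset), {
      idx <- match(sites$population, cent$population)
      jit <- grids[[1]]$cell
      ext <- grid_extent(grids[[1]])
      eps <- grids[[1]]$cell * 1e-6
      sites$lon <- pmin(pmax(cent$lon[idx] + rnorm(nrow(sites), 0, jit),
                             ext["xmin"]), ext["xmax"] - eps)
      sites$lat <- pmin(pmax(cent$lat[idx] + rnorm(nrow(sites), 0, jit),
                             ext["ymin"]), ext["ymax"] - eps)
    })
    sites$id <- paste0(tag, "_", sites$id)
    clim <- extract_at_points(grids, sites)
    sim <- simulate_genotypes(sites, clim, cfg)
    list(genotypes = sim$genotypes, truth = sim$truth, samples = sites,
         climate = clim)
  }
  list(host = one(host_config, "H", 53),
       parasite = one(parasite_config, "A", 59),
       grids = grids)
}

#' Write a simulation truth object to JSON
#' @param truth A `sim_truth`.
#' @param path Output path.
#' @export
write_sim_truth <- function(truth, path) {
  jsonlite::write_json(list(adaptive_ids = truth$adaptive_ids,
                            drivers = as.list(truth$drivers),
                            pop_freq = truth$pop_freq),
                       path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}
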