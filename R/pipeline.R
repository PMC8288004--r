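# End-to-end orchestration: QC -> climate pruning -> three genome scans ->
# consensus -> FST -> GDM per locus subset -> composition maps -> Procrustes
# comparison, with a reproducibility manifest.

#' Run configuration for a species
#'
#' Inputs may be in-memory objects (from the simulator) or file paths.
#'
#' @param genotypes A [genotype_matrix], or a path readable by
#'   [read_snp_table()].
#' @param samples Sample metadata data frame or CSV path (needed with file
#'   input).
#' @param grids Named list of [climate_grid]s (or paths to `.asc` files,
#'   with `grid_groups` naming each variable's group).
#' @param climate Optional precomputed per-sample `climate_table`.
#' @param dialect Genotype file dialect.
#' @param grid_groups Named character vector of groups for file-based grids.
#' @param variables Optional explicit retained-variable list (skips the
#'   Spearman pruning and uses these directly).
#' @param qc List of QC thresholds.
#' @param scan List of scan settings: `K` (NULL = scree rule), `fdr`,
#'   `threshold_db`, `n_pseudo`, `bp` (a [bp_settings()]).
#' @param consensus_min_methods Methods required for the adaptive set.
#' @param gdm List: `n_perm`, `alpha`, `force_retain`.
#' @param outdir Output directory (NULL = keep everything in memory).
#' @param seed Integer seed for the whole run.
#' @param label Species label used in output names.
#' @return A `run_config` list.
#' @export
run_config <- function(genotypes, samples = NULL, grids = NULL,
                       climate = NULL, dialect = "snp-csv",
                       grid_groups = NULL, variables = NULL,
                       qc = list(), scan = list(), consensus_min_methods = 2,
                       gdm = list(), outdir = NULL, seed = 1,
                       label = "species") {
  qc <- utils::modifyList(list(max_missing_loci = 0.05, min_repro = 0.98,
                               min_maf = 0.05, max_missing_ind = 0.20), qc)
  scan <- utils::modifyList(list(K = NULL, fdr = 0.05, threshold_db = 20,
                                 n_pseudo = 1000, bp = bp_settings()), scan)
  gdm <- utils::modifyList(list(n_perm = 500, alpha = 0.05,
                                force_retain = NULL), gdm)
  structure(list(genotypes = genotypes, samples = samples, grids = grids,
                 climate = climate, dialect = dialect,
                 grid_groups = grid_groups, variables = variables, qc = qc,
                 scan = scan, consensus_min_methods = consensus_min_methods,
                 gdm = gdm, outdir = outdir, seed = seed, label = label),
            class = "run_config")
}

load_inputs <- function(config) {
  g <- config$genotypes
  if (is.character(g))
    g <- read_snp_table(g, config$dialect, samples = config$samples)
  grids <- config$grids
  if (is.character(grids)) {
    groups <- config$grid_groups
    grids <- setNames(lapply(seq_along(grids), function(i)
      read_ascii_grid(grids[i],
                      name = names(grids)[i] %||%
                        sub("\\.asc$", "", basename(grids[i])),
                      group = groups[[i]])), names(grids))
  }
  list(genotypes = g, grids = grids)
}

#' Run the full per-species analysis
#'
#' Executes QC, climate extraction and collinearity pruning, the three
#' genome scans, the consensus partition, Weir-Cockerham FST on the neutral
#' and adaptive locus sets, GDM fitting with permutation-based backward
#' elimination per set, deviance partitioning, and genetic-composition maps
#' with the neutral-vs-adaptive Procrustes comparison. All stage outputs
#' are returned in a bundle (and written to `outdir` when set, together
#' with a reproducibility manifest of every threshold and seed consumed).
#'
#' @param config A [run_config()].
#' @return A `species_bundle` list with elements `qc`, `climate`, `scans`,
#'   `partition`, `fst`, `gdm`, `maps`, `procrustes`, `manifest`.
#' @export
run_species <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 2)
    t0 <<- t1
  }
  inputs <- load_inputs(config)
  g_raw <- inputs$genotypes
  grids <- inputs$grids

  # --- QC ---
  qc <- qc_pipeline(g_raw, config$qc$max_missing_loci, config$qc$min_repro,
                    config$qc$min_maf, config$qc$max_missing_ind,
                    seed = sub_seed(seed, 1))
  g <- qc$genotypes
  tick("qc")

  # --- climate ---
  clim <- config$climate %||% extract_at_points(grids, g$samples)
  clim <- clim[match(g$samples$id, clim$sample_id), , drop = FALSE]
  groups_attr <- attr(config$climate %||% clim, "groups")
  attr(clim, "groups") <- groups_attr
  if (is.null(config$variables)) {
    retained <- c(spearman_prune(clim, "temperature"),
                  spearman_prune(clim, "precipitation"))
  } else retained <- config$variables
  popenv <- population_means(clim, g$samples, variables = retained)
  env_ind <- as.matrix(clim[retained])
  rownames(env_ind) <- clim$sample_id
  tick("climate")

  # --- scans ---
  Y_imp <- impute_mean(g$counts)
  K <- config$scan$K
  if (is.null(K)) {
    p_hat <- colMeans(Y_imp) / 2
    usable <- p_hat > 0 & p_hat < 1
    Ys <- scale(Y_imp[, usable, drop = FALSE], center = 2 * p_hat[usable],
                scale = sqrt(2 * p_hat[usable] * (1 - p_hat[usable])))
    ev <- svd(Ys, nu = 0, nv = 0)$d^2 / (nrow(Ys) - 1)
    K <- choose_k_scree(ev, k_max = min(10, length(ev)))
  }
  scan_pca <- pca_outlier_scan(g, K = K, fdr = config$scan$fdr)
  g_complete <- lfmm_impute(g, K = K)
  scan_lfmm <- lfmm_ridge_scan(structure(list(counts = g_complete,
                                              loci = g$loci,
                                              samples = g$samples),
                                         class = "genotype_matrix"),
                               env_ind, K = K, fdr = config$scan$fdr)
  bayes <- bayes_scan(g, popenv$env, settings = config$scan$bp,
                      threshold_db = config$scan$threshold_db,
                      n_pseudo = config$scan$n_pseudo,
                      seed = sub_seed(seed, 2))
  scans <- list(pca = scan_pca, lfmm = scan_lfmm, bayes = bayes$scan)
  tick("scans")

  # --- consensus ---
  partition <- partition_loci(scans, config$consensus_min_methods)
  tick("consensus")

  # --- FST ---
  fst <- list()
  for (set in c("neutral", "adaptive")) {
    ids <- partition[[set]]
    if (length(ids) >= 2) fst[[set]] <- pairwise_fst(g, ids)
  }
  tick("fst")

  # --- GDM per locus set ---
  geo_groups <- list(geographic = "geographic",
                     temperature = retained[groups_attr[retained] == "temperature"],
                     precipitation = retained[groups_attr[retained] == "precipitation"])
  gdm_out <- list()
  for (set in names(fst)) {
    res <- try({
      scaled <- scale_unit(fst[[set]])
      pt <- build_pair_table(scaled, popenv$env, popenv$coords)
      model <- backward_eliminate(pt, n_perm = config$gdm$n_perm,
                                  alpha = config$gdm$alpha,
                                  seed = sub_seed(seed, 3 + match(set, names(fst))),
                                  force_retain = config$gdm$force_retain)
      part <- if (length(model$predictors) > 0 && model$pct_explained > 0) {
        grp <- lapply(names(geo_groups), function(nm)
          intersect(geo_groups[[nm]], model$predictors))
        names(grp) <- names(geo_groups)
        partition_deviance(pt, grp)
      } else NULL
      list(model = model, importance = gdm_importance(model),
           partition = part, pair_table = pt)
    }, silent = TRUE)
    if (!inherits(res, "try-error")) gdm_out[[set]] <- res
    else message("GDM stage skipped for ", set, " set: ",
                 attr(res, "condition")$message)
  }
  tick("gdm")

  # --- maps & Procrustes ---
  maps <- list()
  if (!is.null(grids)) {
    for (set in names(gdm_out)) {
      model <- gdm_out[[set]]$model
      if (length(setdiff(model$predictors, "geographic")) >= 1) {
        surf <- transform_grid(model, grids)
        maps[[set]] <- pca_rgb(surf)
      }
    }
  }
  procrustes <- if (!is.null(maps$neutral) && !is.null(maps$adaptive))
    procrustes_residuals(maps$neutral, maps$adaptive) else NULL
  tick("maps")

  manifest <- list(package_version = as.character(utils::packageVersion("landgen")),
                   label = config$label, seed = seed,
                   qc_thresholds = config$qc,
                   scan_settings = list(K = K, fdr = config$scan$fdr,
                                        threshold_db = config$scan$threshold_db,
                                        n_pseudo = config$scan$n_pseudo,
                                        mcmc = unclass(config$scan$bp)),
                   consensus_min_methods = config$consensus_min_methods,
                   gdm_settings = config$gdm,
                   retained_variables = retained,
                   stage_seconds = as.list(timings))
  bundle <- structure(list(label = config$label, qc = qc$report,
                           genotypes = g, climate = clim, popenv = popenv,
                           retained_variables = retained, K = K,
                           scans = scans, bayes = bayes,
                           partition = partition, fst = fst, gdm = gdm_out,
                           maps = maps, procrustes = procrustes,
                           grids = grids, manifest = manifest),
                      class = "species_bundle")
  if (!is.null(config$outdir)) write_bundle(bundle, config$outdir)
  bundle
}

#' @export
print.species_bundle <- function(x, ...) {
  cat(sprintf("<species_bundle> %s: %d loci post-QC; adaptive %d / neutral %d\n",
              x$label, ncol(x$genotypes$counts), length(x$partition$adaptive),
              length(x$partition$neutral)))
  invisible(x)
}

write_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pfx <- function(name) file.path(outdir, paste0(bundle$label, "_", name))
  write_qc_report(bundle$qc, pfx("qc_report.json"))
  write_snp_table(bundle$genotypes, pfx("genotypes_postqc.csv"))
  write_sample_table(bundle$genotypes$samples, pfx("samples.csv"))
  write.csv(bundle$climate, pfx("climate.csv"), row.names = FALSE)
  for (nm in names(bundle$scans))
    write_scan_result(bundle$scans[[nm]], pfx(paste0("scan_", nm, ".csv")))
  write_partition(bundle$partition, pfx("partition.json"))
  for (set in names(bundle$fst))
    write_fst_matrix(bundle$fst[[set]], pfx(paste0("fst_", set, ".csv")))
  for (set in names(bundle$gdm)) {
    m <- bundle$gdm[[set]]$model
    jsonlite::write_json(list(predictors = m$predictors,
                              intercept = m$intercept,
                              coef = as.data.frame(m$coef),
                              deviance = m$deviance,
                              null_deviance = m$null_deviance,
                              pct_explained = m$pct_explained,
                              perm_pvalues = as.list(m$perm_pvalues),
                              importance = as.list(gdm_importance(m))),
                         pfx(paste0("gdm_", set, ".json")),
                         auto_unbox = TRUE, digits = NA)
    if (length(m$predictors) > 0)
      write.csv(gdm_splines(m), pfx(paste0("gdm_", set, "_splines.csv")),
                row.names = FALSE)
    if (!is.null(bundle$gdm[[set]]$partition))
      write.csv(bundle$gdm[[set]]$partition$components,
                pfx(paste0("gdm_", set, "_partition.csv")), row.names = FALSE)
  }
  for (set in names(bundle$maps))
    write_composition_png(bundle$maps[[set]], pfx(paste0("map_", set, ".png")))
  if (!is.null(bundle$procrustes)) {
    write_ascii_grid(residual_grid(bundle$procrustes),
                     pfx("procrustes_residuals.asc"))
    jsonlite::write_json(list(scale = bundle$procrustes$scale,
                              rss = bundle$procrustes$rss,
                              residual_summary =
                                as.list(summary(bundle$procrustes$residuals))),
                         pfx("procrustes.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(bundle$manifest, file.path(outdir,
                                                  paste0(bundle$label, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Compare two completed species runs
#'
#' Cross-species comparison of the neutral-vs-adaptive composition-map
#' Procrustes residuals (scaled jointly by the pooled min/max) and of the
#' deviance-partitioning tables, with a summary contrasting the temperature
#' and precipitation explained-deviance shares per species.
#'
#' @param bundle_a,bundle_b `species_bundle`s over the same climate grids.
#' @return A `species_comparison` list.
#' @export
compare_species <- function(bundle_a, bundle_b) {
  if (!is.null(bundle_a$grids) && !is.null(bundle_b$grids)) {
    ga <- bundle_a$grids[[1]]; gb <- bundle_b$grids[[1]]
    if (!isTRUE(all.equal(dim(ga$values), dim(gb$values))) ||
        ga$x0 != gb$x0 || ga$y0 != gb$y0 || ga$cell != gb$cell)
      stopf("species bundles use different climate grids")
  }
  scaled <- NULL
  if (!is.null(bundle_a$procrustes) && !is.null(bundle_b$procrustes))
    scaled <- scale_residuals_across(bundle_a$procrustes$residuals,
                                     bundle_b$procrustes$residuals)
  share_tab <- do.call(rbind, lapply(list(bundle_a, bundle_b), function(b) {
    part <- b$gdm$adaptive$partition
    data.frame(species = b$label,
               geographic = if (is.null(part)) NA else
                 group_share(part, "geographic"),
               temperature = if (is.null(part)) NA else
                 group_share(part, "temperature"),
               precipitation = if (is.null(part)) NA else
                 group_share(part, "precipitation"),
               stringsAsFactors = FALSE)
  }))
  structure(list(labels = c(bundle_a$label, bundle_b$label),
                 scaled_residuals = scaled,
                 residual_scale_range = if (is.null(scaled)) NULL else
                   c(min = scaled$min, max = scaled$max),
                 adaptive_climate_shares = share_tab,
                 partitions = list(a = bundle_a$gdm$adaptive$partition,
                                   b = bundle_b$gdm$adaptive$partition)),
            class = "species_comparison")
}

#' @export
print.species_comparison <- function(x, ...) {
  cat(sprintf("<species_comparison> %s vs %s\n", x$labels[1], x$labels[2]))
  print(x$adaptive_climate_shares, row.names = FALSE)
  invisible(x)
}

#' Simulate a paired host/parasite data set and run the full analysis
#'
#' Convenience wrapper for the package's paired study design: simulates the
#' default host/parasite pair for one seed, runs the complete per-species
#' analysis on both, and returns the bundles together with the simulation
#' truth. Chain lengths and permutation counts default to desk-scale
#' settings (see the methods vignette).
#'
#' @param seed Integer seed driving the simulation and both runs.
#' @param bp MCMC settings for the Bayesian scan.
#' @param n_perm GDM permutations for backward elimination.
#' @param null_effect If `TRUE`, both species are simulated with all
#'   adaptive effect sizes set to zero (a null data set).
#' @param species Which species to analyse (both by default).
#' @return List with `host`, `parasite` (each `bundle` + `truth`) and the
#'   shared `grids`.
#' @export
replicate_pair_analysis <- function(seed,
                                    bp = bp_settings(n_iter = 2500,
                                                     burnin = 1250,
                                                     npilot = 6,
                                                     pilotlength = 250,
                                                     thin = 5, n_chains = 2),
                                    n_perm = 200, null_effect = FALSE,
                                    species = c("host", "parasite")) {
  setup <- default_pair_setup(seed)
  if (null_effect) {
    setup$host_config$effect_beta <- 0
    setup$parasite_config$effect_beta <- 0
  }
  pair <- simulate_pair(setup$host_config, setup$parasite_config,
                        setup$grids, seed = seed)
  out <- list(grids = pair$grids)
  for (sp in species) {
    cfg <- run_config(pair[[sp]]$genotypes, grids = pair$grids,
                      climate = pair[[sp]]$climate,
                      scan = list(bp = bp), gdm = list(n_perm = n_perm),
                      seed = sub_seed(seed, 900 + match(sp, c("host", "parasite"))),
                      label = sp)
    out[[sp]] <- list(bundle = run_species(cfg), truth = pair[[sp]]$truth)
  }
  out
}

#' Fraction of planted adaptive loci recovered by the consensus
#'
#' Power is measured among planted loci that survive QC and fragment
#' thinning (one SNP per fragment can legitimately discard a planted SNP
#' before any scan sees it).
#'
#' @param bundle A `species_bundle`.
#' @param truth The matching `sim_truth`.
#' @return List: `n_surviving`, `n_recovered`, `power`.
#' @export
consensus_power <- function(bundle, truth) {
  surviving <- intersect(truth$adaptive_ids, bundle$genotypes$loci$id)
  rec <- sum(surviving %in% bundle$partition$adaptive)
  list(n_surviving = length(surviving), n_recovered = rec,
       power = if (length(surviving) > 0) rec / length(surviving) else NA)
}
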