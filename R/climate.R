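# Climate predictor handling: collinearity pruning within variable groups
# and population-level predictor means.

#' Prune collinear variables within a group by Spearman correlation
#'
#' Repeatedly drops the variable with the largest mean absolute within-group
#' Spearman correlation until no retained pair has `|rho| >= threshold`.
#' Ties are broken by dropping the variable later in input order, making the
#' rule deterministic.
#'
#' @param table A `climate_table` from [extract_at_points()] (or any data
#'   frame with a `groups` attribute naming each variable's group).
#' @param group Group to prune (`"temperature"` or `"precipitation"`).
#' @param threshold Correlation threshold (default 0.8).
#' @return Character vector of retained variable names within the group.
#' @export
spearman_prune <- function(table, group, threshold = 0.8) {
  groups <- attr(table, "groups")
  vars <- names(groups)[groups == group]
  assert_that(length(vars) >= 1, "no variables in group '%s'", group)
  n <- nrow(table)
  assert_that(n >= 3, "need at least 3 samples for rank correlation")
  if (length(vars) == 1) return(vars)
  keep <- vars
  repeat {
    cm <- abs(cor(table[keep], method = "spearman"))
    diag(cm) <- 0
    if (all(cm < threshold, na.rm = TRUE)) break
    score <- rowMeans(cm)
    # largest mean |rho|; ties -> later in input order
    worst <- keep[score >= max(score) - 1e-12]
    drop <- worst[which.max(match(worst, vars))]
    keep <- setdiff(keep, drop)
    if (length(keep) == 1) break
  }
  keep
}

#' Population-level predictor means and centroids
#'
#' @param table A `climate_table` (per-sample values).
#' @param samples Sample data frame with `id`, `population`, `lon`, `lat`.
#' @param variables Variables to keep (default: all in the table).
#' @return List: `env` (population x variable matrix of arithmetic means),
#'   `coords` (population x `lon`/`lat` centroid matrix), and `groups`.
#' @export
population_means <- function(table, samples, variables = NULL) {
  idx <- match(samples$id, table$sample_id)
  if (anyNA(idx)) stopf("samples without climate values")
  variables <- variables %||% setdiff(names(table), "sample_id")
  pops <- sort(unique(samples$population))
  assert_that(!anyNA(samples$population) && length(pops) >= 1,
              "every sample needs a population")
  env <- sapply(variables, function(v)
    tapply(table[[v]][idx], samples$population, mean)[pops])
  env <- matrix(env, nrow = length(pops),
                dimnames = list(pops, variables))
  coords <- cbind(lon = tapply(samples$lon, samples$population, mean)[pops],
                  lat = tapply(samples$lat, samples$population, mean)[pops])
  groups <- attr(table, "groups")
  list(env = env, coords = coords,
       groups = if (!is.null(groups)) groups[variables] else NULL)
}
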