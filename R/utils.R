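#' @useDynLib landgen, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median mad quantile rbeta rbinom rnorm runif setNames
#'   aggregate cor prcomp pchisq qchisq p.adjust plogis sd var
#' @importFrom utils read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library code never disturbs the session stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic sub-stream seeds: one user-facing seed drives all stages, each
# stage takes a fixed offset. Kept below 2^31 - 1.
sub_seed <- function(seed, offset) {
  ((as.numeric(seed) %% 1e6) * 2011 + offset * 104729) %% 2147483647
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(cond, ...) if (!isTRUE(cond)) stopf(...)
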