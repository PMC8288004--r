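# Consensus partition of loci across genome-scan methods.

#' Partition loci by genome-scan consensus
#'
#' A locus counts for a method if it is significant under any of that
#' method's variables (multiple significant variables within one method
#' count once). Putatively adaptive loci are significant in two or more
#' methods; putatively neutral loci in none; the rest are single-method
#' detections, excluded from both sets.
#'
#' @param scan_results List of `scan_result` objects over the same locus
#'   set (>= 2).
#' @param min_methods Methods required for the adaptive set (default 2).
#' @return A `consensus_partition`: `adaptive`, `neutral`, `single_method`
#'   locus-id vectors, `per_method` significant sets, and `venn` region
#'   counts.
#' @export
partition_loci <- function(scan_results, min_methods = 2) {
  assert_that(length(scan_results) >= 2, "need at least two scan results")
  ids <- lapply(scan_results, function(s) s$loci$locus_id)
  all_ids <- ids[[1]]
  for (i in seq_along(ids)[-1])
    if (!identical(sort(ids[[i]]), sort(all_ids)))
      stopf("scan results cover different locus sets")
  methods <- vapply(scan_results, `[[`, "", "method")
  sig <- lapply(scan_results, significant_ids)
  names(sig) <- methods
  n_hits <- rowSums(sapply(sig, function(s) all_ids %in% s))
  adaptive <- all_ids[n_hits >= min_methods]
  neutral <- all_ids[n_hits == 0]
  single <- all_ids[n_hits > 0 & n_hits < min_methods]
  # Venn region counts over the method membership patterns
  pat <- apply(sapply(sig, function(s) all_ids %in% s), 1, function(r)
    paste(methods[r], collapse = "&"))
  venn <- table(pat[pat != ""])
  structure(list(adaptive = adaptive, neutral = neutral,
                 single_method = single, per_method = sig,
                 venn = venn, min_methods = min_methods),
            class = "consensus_partition")
}

#' @export
print.consensus_partition <- function(x, ...) {
  cat(sprintf("<consensus_partition> adaptive %d | single-method %d | neutral %d\n",
              length(x$adaptive), length(x$single_method), length(x$neutral)))
  invisible(x)
}

#' Write a consensus partition as JSON (with Venn counts as CSV alongside)
#' @param x A `consensus_partition`.
#' @param path JSON output path; Venn counts go to `sub("json$", "venn.csv", path)`.
#' @export
write_partition <- function(x, path) {
  jsonlite::write_json(list(adaptive = x$adaptive, neutral = x$neutral,
                            single_method = x$single_method,
                            per_method = x$per_method),
                       path, auto_unbox = FALSE, digits = NA)
  venn_df <- data.frame(region = names(x$venn), count = as.integer(x$venn))
  write.csv(venn_df, sub("json$", "venn.csv", path), row.names = FALSE)
  invisible(path)
}
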