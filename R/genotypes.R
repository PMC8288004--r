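# Genotype container and quality-control filters. Counts are biallelic
# dosages: 0 = homozygous reference, 1 = heterozygous, 2 = homozygous
# alternate, NA = missing. Filters follow the fixed order: per-locus call
# rate, reproducibility, minor allele frequency, then per-individual call
# rate, then one randomly chosen SNP per fragment. All thresholds are strict
# inequalities.

#' Construct a genotype matrix
#'
#' @param counts Integer matrix (individuals x loci) over `{0, 1, 2, NA}`.
#' @param samples Data frame `id`, `population`, `lon`, `lat` (one row per
#'   matrix row).
#' @param loci Data frame `id`, `fragment_id`, `reproducibility` (one row
#'   per matrix column). Missing reproducibility defaults to 1, missing
#'   fragment to the locus id.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(counts, samples, loci) {
  counts <- as.matrix(counts)
  assert_that(nrow(counts) == nrow(samples),
              "counts rows must match samples rows")
  assert_that(ncol(counts) == nrow(loci), "counts cols must match loci rows")
  assert_that(!anyDuplicated(samples$id), "sample ids must be unique")
  assert_that(!anyDuplicated(loci$id), "locus ids must be unique")
  ok <- counts %in% c(0L, 1L, 2L) | is.na(counts)
  assert_that(all(ok), "genotype values must be 0, 1, 2 or NA")
  if (is.null(loci$reproducibility)) loci$reproducibility <- 1
  if (is.null(loci$fragment_id)) loci$fragment_id <- loci$id
  loci$reproducibility[is.na(loci$reproducibility)] <- 1
  rownames(counts) <- samples$id
  colnames(counts) <- loci$id
  structure(list(counts = counts, samples = samples, loci = loci),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d loci, %d populations, %.2f%% missing\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$samples$population)),
              100 * global_missing_rate(x)))
  invisible(x)
}

#' Fraction of missing genotype calls
#' @param g A [genotype_matrix].
#' @return Missing cells / total cells.
#' @export
global_missing_rate <- function(g) {
  assert_that(length(g$counts) > 0, "empty genotype matrix")
  mean(is.na(g$counts))
}

subset_genotypes <- function(g, samples = NULL, loci = NULL) {
  samples <- samples %||% seq_len(nrow(g$counts))
  loci <- loci %||% seq_len(ncol(g$counts))
  genotype_matrix(g$counts[samples, loci, drop = FALSE],
                  g$samples[samples, , drop = FALSE],
                  g$loci[loci, , drop = FALSE])
}

locus_maf <- function(counts) {
  p <- colMeans(counts, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Filter loci on call rate, reproducibility and minor allele frequency
#'
#' Filters are applied in a fixed order: (1) loci with missing fraction
#' strictly below `max_missing`; (2) reproducibility strictly above
#' `min_repro`; (3) minor allele frequency (over non-missing calls) strictly
#' above `min_maf`.
#'
#' @param g A [genotype_matrix].
#' @param max_missing,min_repro,min_maf Thresholds in `[0, 1]`.
#' @return List: `genotypes` (filtered) and `removed` (counts removed per
#'   stage).
#' @export
filter_loci <- function(g, max_missing = 0.05, min_repro = 0.98,
                        min_maf = 0.05) {
  for (th in c(max_missing, min_repro, min_maf))
    assert_that(th >= 0 && th <= 1, "thresholds must be in [0, 1]")
  n0 <- ncol(g$counts)
  keep1 <- colMeans(is.na(g$counts)) < max_missing
  g <- subset_genotypes(g, loci = which(keep1))
  n1 <- ncol(g$counts)
  keep2 <- g$loci$reproducibility > min_repro
  g <- subset_genotypes(g, loci = which(keep2))
  n2 <- ncol(g$counts)
  keep3 <- locus_maf(g$counts) > min_maf
  g <- subset_genotypes(g, loci = which(keep3))
  n3 <- ncol(g$counts)
  if (n3 == 0) stopf("no loci left after filtering")
  list(genotypes = g,
       removed = c(call_rate = n0 - n1, reproducibility = n1 - n2,
                   maf = n2 - n3))
}

#' Filter individuals on missing-data fraction
#'
#' Retains individuals whose missing fraction across current loci is
#' strictly below `max_missing`.
#'
#' @param g A [genotype_matrix].
#' @param max_missing Threshold in `[0, 1]`.
#' @return List: `genotypes` and `removed_ids`.
#' @export
filter_individuals <- function(g, max_missing = 0.20) {
  assert_that(max_missing >= 0 && max_missing <= 1,
              "threshold must be in [0, 1]")
  keep <- rowMeans(is.na(g$counts)) < max_missing
  if (!any(keep)) stopf("all individuals removed by missing-data filter")
  list(genotypes = subset_genotypes(g, samples = which(keep)),
       removed_ids = g$samples$id[!keep])
}

#' Retain one randomly selected SNP per fragment
#'
#' @param g A [genotype_matrix].
#' @param seed Integer seed for the uniform selection.
#' @return A [genotype_matrix] with exactly one locus per fragment.
#' @export
thin_one_per_fragment <- function(g, seed = 1) {
  frag <- g$loci$fragment_id
  keep <- with_seed(sub_seed(seed, 61), {
    idx <- split(seq_along(frag), frag)
    sort(vapply(idx, function(i) if (length(i) == 1) i else
      i[sample.int(length(i), 1)], integer(1)))
  })
  subset_genotypes(g, loci = keep)
}

#' Run the full QC filter chain
#'
#' Locus filters (call rate, reproducibility, MAF), then the individual
#' filter, then one-SNP-per-fragment thinning, with a reconciled report.
#'
#' @param g A [genotype_matrix].
#' @param max_missing_loci,min_repro,min_maf,max_missing_ind Thresholds.
#' @param seed Seed for fragment thinning.
#' @return List: `genotypes` and `report` (a `qc_report` list).
#' @export
qc_pipeline <- function(g, max_missing_loci = 0.05, min_repro = 0.98,
                        min_maf = 0.05, max_missing_ind = 0.20, seed = 1) {
  n_loci0 <- ncol(g$counts); n_ind0 <- nrow(g$counts)
  fl <- filter_loci(g, max_missing_loci, min_repro, min_maf)
  fi <- filter_individuals(fl$genotypes, max_missing_ind)
  th <- thin_one_per_fragment(fi$genotypes, seed)
  report <- structure(list(
    input = c(individuals = n_ind0, loci = n_loci0),
    loci_removed = as.list(fl$removed),
    loci_removed_thinning = ncol(fi$genotypes$counts) - ncol(th$counts),
    individuals_removed = length(fi$removed_ids),
    removed_individual_ids = fi$removed_ids,
    output = c(individuals = nrow(th$counts), loci = ncol(th$counts)),
    global_missing_rate = global_missing_rate(th)), class = "qc_report")
  list(genotypes = th, report = report)
}

#' Write a QC report as JSON
#' @param report A `qc_report`.
#' @param path Output path.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a genotype matrix in the SNP-table CSV dialect
#'
#' Header row: `locus_id, fragment_id, reproducibility`, then sample ids.
#' One row per locus; missing calls written as `-`.
#'
#' @param g A [genotype_matrix].
#' @param path Output path.
#' @export
write_snp_table <- function(g, path) {
  m <- t(g$counts)
  m[is.na(m)] <- "-"
  df <- data.frame(locus_id = g$loci$id, fragment_id = g$loci$fragment_id,
                   reproducibility = g$loci$reproducibility, m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write sample metadata CSV
#' @param samples Sample data frame (`id`, `population`, `lon`, `lat`).
#' @param path Output path.
#' @export
write_sample_table <- function(samples, path) {
  write.csv(samples[c("id", "population", "lon", "lat")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read sample metadata CSV
#' @param path File path.
#' @return Sample data frame.
#' @export
read_sample_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read SNP data from the SNP-table CSV dialect or a VCF
#'
#' For VCF input, genotypes come from the `GT` field; non-biallelic records
#' are skipped with a message. Samples present in `samples` get population
#' and coordinate metadata attached.
#'
#' @param path Genotype file path.
#' @param dialect `"snp-csv"` or `"vcf"`.
#' @param samples Optional sample metadata data frame (or CSV path) with
#'   `id`, `population`, `lon`, `lat`.
#' @return A [genotype_matrix].
#' @export
read_snp_table <- function(path, dialect = c("snp-csv", "vcf"),
                           samples = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (is.character(samples)) samples <- read_sample_table(samples)
  if (dialect == "snp-csv") {
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
    need <- c("locus_id", "fragment_id", "reproducibility")
    if (!all(need %in% names(df)))
      stopf("malformed SNP table: missing columns %s",
            paste(setdiff(need, names(df)), collapse = ", "))
    ids <- setdiff(names(df), need)
    cnt <- as.matrix(df[ids])
    cnt[cnt == "-"] <- NA
    badm <- matrix(!(cnt %in% c("0", "1", "2") | is.na(cnt)),
                   nrow(cnt), ncol(cnt))
    if (any(badm))
      stopf("malformed genotype at line %d of %s",
            which(rowSums(badm) > 0)[1] + 1L, path)
    counts <- t(matrix(as.integer(cnt), nrow(df), length(ids),
                       dimnames = list(df$locus_id, ids)))
    loci <- data.frame(id = df$locus_id, fragment_id = df$fragment_id,
                       reproducibility = as.numeric(df$reproducibility),
                       stringsAsFactors = FALSE)
  } else {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    biall <- !grepl(",", fix[, "ALT"]) & nchar(fix[, "REF"]) == 1 &
      nchar(fix[, "ALT"]) == 1 & !is.na(fix[, "ALT"])
    if (any(!biall))
      message(sum(!biall), " non-biallelic VCF records skipped")
    gt <- vcfR::extract.gt(vcf)[biall, , drop = FALSE]
    ids <- fix[biall, "ID"]
    ids[is.na(ids) | ids == "."] <-
      paste0(fix[biall, "CHROM"], "_", fix[biall, "POS"])[is.na(ids) | ids == "."]
    code <- function(x) {
      x <- gsub("\\|", "/", x)
      out <- rep(NA_integer_, length(x))
      out[x %in% c("0/0")] <- 0L
      out[x %in% c("0/1", "1/0")] <- 1L
      out[x %in% c("1/1")] <- 2L
      out
    }
    counts <- t(matrix(code(as.vector(gt)), nrow(gt), ncol(gt)))
    rownames(counts) <- colnames(gt)
    colnames(counts) <- ids
    loci <- data.frame(id = ids, fragment_id = ids, reproducibility = 1,
                       stringsAsFactors = FALSE)
  }
  sample_ids <- rownames(counts)
  if (is.null(samples)) {
    samples <- data.frame(id = sample_ids, population = NA_character_,
                          lon = NA_real_, lat = NA_real_,
                          stringsAsFactors = FALSE)
  } else {
    samples <- samples[match(sample_ids, samples$id), , drop = FALSE]
    if (anyNA(samples$id))
      stopf("sample metadata missing for: %s",
            paste(sample_ids[is.na(samples$id)], collapse = ", "))
  }
  genotype_matrix(counts, samples, loci)
}
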