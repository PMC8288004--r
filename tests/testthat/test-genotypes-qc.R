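# SNP I/O and the fixed-order QC filter chain.

test_that("snp-table CSV round-trips counts and metadata", {
  sm <- small_sim(seed = 4, n_neutral = 60, n_adaptive = 0)
  g <- sm$genotypes
  path <- tempfile(fileext = ".csv")
  write_snp_table(g, path)
  spath <- tempfile(fileext = ".csv")
  write_sample_table(g$samples, spath)
  g2 <- read_snp_table(path, "snp-csv", samples = spath)
  expect_identical(unname(g2$counts), unname(g$counts))
  expect_equal(g2$loci$reproducibility, g$loci$reproducibility,
               tolerance = 1e-12)
  expect_identical(g2$loci$fragment_id, g$loci$fragment_id)
  expect_identical(g2$samples$population, g$samples$population)
})

test_that("hand-written 3-sample 2-locus CSV parses to the stated matrix", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("locus_id,fragment_id,reproducibility,s1,s2,s3",
               "loc1,f1,0.99,0,1,2",
               "loc2,f2,1.0,-,2,0"), path)
  g <- read_snp_table(path, "snp-csv")
  expect_equal(dim(g$counts), c(3L, 2L))
  expect_identical(g$counts[, "loc1"], c(s1 = 0L, s2 = 1L, s3 = 2L))
  expect_identical(g$counts[, "loc2"], c(s1 = NA_integer_, s2 = 2L, s3 = 0L))
})

test_that("malformed rows are reported with their line number", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("locus_id,fragment_id,reproducibility,s1",
               "loc1,f1,0.99,0",
               "loc2,f2,1.0,7"), path)
  expect_error(read_snp_table(path, "snp-csv"), "line 3")
})

test_that("VCF input codes GT correctly and skips multi-allelic records", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
               "1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1",
               "1\t200\tv2\tC\tT\t.\tPASS\t.\tGT\t1/1\t./.",
               "1\t300\tv3\tG\tA,C\t.\tPASS\t.\tGT\t1/2\t0/0"), path)
  expect_message(g <- read_snp_table(path, "vcf"), "1 non-biallelic")
  expect_equal(dim(g$counts), c(2L, 2L))
  expect_identical(g$counts[, "v1"], c(s1 = 0L, s2 = 1L))
  expect_identical(g$counts[, "v2"], c(s1 = 2L, s2 = NA_integer_))
  expect_equal(g$loci$reproducibility, c(1, 1))
})

test_that("locus filters use strict thresholds in the documented order", {
  # 4 loci: missing 0 / 0.1 / 0 / 0; repro 1 / 1 / 0.97 / 1;
  # MAF 0.3 / 0.3 / 0.3 / 0.04 -> exactly one survivor
  counts <- matrix(0L, 10, 4)
  counts[, 1] <- rep(c(0L, 1L), 5)                     # MAF 0.25 > 0.05
  counts[, 2] <- rep(c(0L, 1L), 5); counts[1, 2] <- NA # 10% missing
  counts[, 3] <- rep(c(0L, 1L), 5)                     # low repro
  counts[1, 4] <- 1L                                   # MAF 0.05 (not >)
  g <- genotype_matrix(counts,
                       data.frame(id = sprintf("s%02d", 1:10),
                                  population = rep(c("A", "B"), each = 5),
                                  lon = 0, lat = 0),
                       data.frame(id = paste0("L", 1:4),
                                  fragment_id = paste0("F", 1:4),
                                  reproducibility = c(1, 1, 0.97, 1)))
  fl <- filter_loci(g, max_missing = 0.05, min_repro = 0.98, min_maf = 0.05)
  expect_identical(fl$genotypes$loci$id, "L1")
  expect_equal(unname(fl$removed), c(1, 1, 1))
  expect_equal(sum(fl$removed), 3)
})

test_that("a locus with exactly the missing threshold is removed (strict)", {
  counts <- matrix(rep(c(0L, 1L), 10), 20, 2)
  counts[1, 2] <- NA  # exactly 5% missing
  g <- genotype_matrix(counts,
                       data.frame(id = sprintf("s%02d", 1:20),
                                  population = "A", lon = 0, lat = 0),
                       data.frame(id = c("L1", "L2"),
                                  fragment_id = c("F1", "F2"),
                                  reproducibility = 1))
  fl <- filter_loci(g, max_missing = 0.05)
  expect_identical(fl$genotypes$loci$id, "L1")
})

test_that("complete high-MAF matrices pass unchanged; filters are idempotent", {
  sm <- small_sim(seed = 5, n_neutral = 100, n_adaptive = 0,
                  missing_rate = 0)
  g <- sm$genotypes
  g$loci$reproducibility <- 1
  fl <- filter_loci(g)
  fi <- filter_individuals(fl$genotypes)
  # second application changes nothing
  fl2 <- filter_loci(fi$genotypes)
  fi2 <- filter_individuals(fl2$genotypes)
  expect_identical(fl2$genotypes$loci$id, fi$genotypes$loci$id)
  expect_equal(sum(fl2$removed), 0)
  expect_length(fi2$removed_ids, 0)
})

test_that("individual filter removes strictly above-threshold individuals", {
  counts <- matrix(1L, 3, 100)
  counts[, seq(2, 100, by = 2)] <- 0L  # keep MAF up
  counts[1, 1:5] <- NA   # 5%
  counts[2, 1:20] <- NA  # exactly 20% -> removed (strict)
  counts[3, 1:19] <- NA  # 19%
  g <- genotype_matrix(counts,
                       data.frame(id = c("a", "b", "c"), population = "A",
                                  lon = 0, lat = 0),
                       data.frame(id = sprintf("L%03d", 1:100),
                                  fragment_id = sprintf("F%03d", 1:100),
                                  reproducibility = 1))
  fi <- filter_individuals(g, 0.20)
  expect_identical(fi$removed_ids, "b")
})

test_that("fragment thinning keeps one locus per fragment, seed-stable", {
  sm <- small_sim(seed = 6, n_neutral = 200, n_adaptive = 0)
  g <- sm$genotypes
  th1 <- thin_one_per_fragment(g, seed = 3)
  th2 <- thin_one_per_fragment(g, seed = 3)
  th3 <- thin_one_per_fragment(g, seed = 4)
  expect_identical(th1$loci$id, th2$loci$id)
  expect_equal(ncol(th1$counts), length(unique(g$loci$fragment_id)))
  # count is seed-invariant even when the selection differs
  expect_equal(ncol(th3$counts), ncol(th1$counts))
  expect_false(identical(th1$loci$id, th3$loci$id))
  expect_equal(anyDuplicated(th1$loci$fragment_id), 0L)
  # singleton fragments are forced choices
  singles <- names(which(table(g$loci$fragment_id) == 1))
  expect_true(all(g$loci$id[g$loci$fragment_id %in% singles] %in%
                    th1$loci$id))
})

test_that("global missing rate is missing cells over total cells", {
  counts <- matrix(rep(c(0L, 2L), 25), 5, 10)
  counts[1, 1] <- NA
  g <- genotype_matrix(counts,
                       data.frame(id = paste0("s", 1:5), population = "A",
                                  lon = 0, lat = 0),
                       data.frame(id = paste0("L", 1:10),
                                  fragment_id = paste0("F", 1:10),
                                  reproducibility = 1))
  expect_equal(global_missing_rate(g), 0.02)
  g$counts[1, 1] <- 0L
  expect_equal(global_missing_rate(g), 0)
})

test_that("QC pipeline reconciles stage counts and bounds missingness", {
  sm <- small_sim(seed = 7, n_neutral = 400, n_adaptive = 0,
                  missing_rate = 0.012)
  qc <- qc_pipeline(sm$genotypes, seed = 1)
  rep <- qc$report
  expect_equal(rep$input[["loci"]] - sum(unlist(rep$loci_removed)) -
                 rep$loci_removed_thinning, rep$output[["loci"]])
  expect_equal(rep$input[["individuals"]] - rep$individuals_removed,
               rep$output[["individuals"]])
  # QC removes high-missingness loci, so the post-QC rate cannot exceed
  # the generating rate
  expect_lte(rep$global_missing_rate, 0.012)
  expect_gte(rep$global_missing_rate, 0)
  # output loci/samples are subsets of the input
  expect_true(all(qc$genotypes$loci$id %in% sm$genotypes$loci$id))
  expect_true(all(qc$genotypes$samples$id %in% sm$genotypes$samples$id))
})
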