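test_that("fragment loading validates bounds and reports rejections", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("2L\t100\t300", "2L\t500\t700", "X\t0\t150"), bed)
  lib <- load_fragments(bed, "wt", tiny_sizes)
  expect_equal(lib$library_size, 3)
  expect_equal(nrow(lib$fragments), 3L)

  # empty file: empty library, later scaling errors
  writeLines(character(0), bed)
  lib0 <- load_fragments(bed, "wt", tiny_sizes)
  expect_equal(lib0$library_size, 0)
  expect_error(binned_coverage(lib0, tiny_sizes), "empty")

  # record beyond chromosome end is rejected with a report
  writeLines(c("2L\t100\t300", "2L\t9990\t10500"), bed)
  expect_message(lib2 <- load_fragments(bed, "wt", tiny_sizes), "rejected")
  expect_equal(lib2$library_size, 1)
  expect_equal(lib2$n_rejected, 1L)

  # malformed coordinates name the line
  writeLines(c("2L\t100\t300", "2L\tfoo\t400"), bed)
  expect_error(load_fragments(bed, "wt", tiny_sizes), "line")
})

test_that("overlap counting is half-open and matches the spec cases", {
  lib <- fragment_library(
    data.frame(chrom = "2L", start = 100L, end = 200L), "wt")
  abut <- data.frame(interval_id = "iv", chrom = "2L",
                     start = 200L, end = 300L)
  expect_equal(count_overlaps(lib, abut), 0L)  # half-open abutment
  touch <- data.frame(interval_id = "iv", chrom = "2L",
                      start = 199L, end = 300L)
  expect_equal(count_overlaps(lib, touch), 1L)
  empty <- fragment_library(
    data.frame(chrom = character(), start = integer(), end = integer()),
    "none", 0)
  expect_equal(count_overlaps(empty, abut), 0L)
  # one fragment spanning two intervals contributes to both
  span <- fragment_library(
    data.frame(chrom = "2L", start = 150L, end = 450L), "wt")
  two <- data.frame(interval_id = c("a", "b"), chrom = "2L",
                    start = c(100L, 400L), end = c(200L, 500L))
  expect_equal(count_overlaps(span, two), c(1L, 1L))
})

test_that("overlap counting equals the brute-force oracle on random fixtures", {
  for (s in 1:20) {
    set.seed(s)
    frags <- random_fragments(sample(50:1000, 1))
    ivs <- random_intervals(sample(5:50, 1))
    lib <- fragment_library(frags, "wt")
    expect_equal(count_overlaps(lib, ivs), oracle_count_overlaps(frags, ivs))
  }
})

test_that("cpm and cpkm follow the scaling formulas exactly", {
  expect_identical(cpm(10, 1e6), 10)
  expect_identical(cpm(0, 123), 0)
  expect_identical(cpm(7, 350000), 20)
  expect_identical(cpkm(10, 1e6, 2000), 5)
  expect_identical(cpkm(3, 500000, 250), 24)
  expect_error(cpm(1, 0), "positive")
  expect_error(cpkm(1, 10, 0), "positive")
  # cpkm invariant under joint rescaling of counts and library size
  expect_equal(cpkm(7, 2e5, 1500), cpkm(7 * 13, 2e5 * 13, 1500))
})

test_that("genotype z-scores use population SD, center, and are affine-invariant", {
  m <- rbind(c(5, 5, 5), c(0, 0, 3), c(1, 2, 9))
  colnames(m) <- c("bam", "aly", "wildtype")
  z <- genotype_zscores(m)
  expect_equal(unname(z[1, ]), c(0, 0, 0))
  expect_equal(unname(z[2, ]), c(-0.707, -0.707, 1.414), tolerance = 1e-3)
  expect_true(all(abs(rowSums(z)) < 1e-9))
  # invariant under x -> a x + b, a > 0
  z2 <- genotype_zscores(3.7 * m + 11, c("bam", "aly", "wildtype"))
  expect_equal(z, z2)
  expect_error(genotype_zscores(m[, 1:2, drop = FALSE]), "missing")
})

test_that("score_table assembles per-library raw/cpm/cpkm columns", {
  frags <- data.frame(chrom = c("2L", "2L", "X"),
                      start = c(100L, 150L, 200L),
                      end = c(300L, 350L, 400L))
  lib <- fragment_library(frags, "wt", library_size = 4)  # one unstored
  ivs <- data.frame(interval_id = c("a", "b"), chrom = c("2L", "X"),
                    start = c(0L, 0L), end = c(1000L, 500L))
  st <- score_table(list(lib), ivs)
  expect_equal(st$raw_wt, c(2L, 1L))
  expect_equal(st$cpm_wt, c(2, 1) * 1e6 / 4)
  expect_equal(st$cpkm_wt, c(2 / 1, 1 / 0.5) * 1e6 / 4)
})

test_that("transposon scoring treats each consensus as one full-length interval", {
  sizes <- c("2L" = 10000L, "TE1_consensus" = 5000L)
  frags <- data.frame(chrom = rep("TE1_consensus", 25),
                      start = 0:24 * 100L, end = 0:24 * 100L + 80L)
  lib <- fragment_library(frags, "wt", library_size = 1e6)
  ts <- transposon_scores(lib, c(TE1_consensus = 5000L), sizes)
  expect_equal(ts$raw, 25L)
  expect_equal(ts$cpkm, 5)       # 25 * 1e6 / (1e6 * 5)
  # absent consensus scores zero; unknown consensus errors
  ts2 <- transposon_scores(
    fragment_library(frags[0, ], "wt", 10), c(TE1_consensus = 5000L), sizes)
  expect_equal(ts2$raw, 0L)
  expect_error(transposon_scores(lib, c(TEX = 100L), sizes), "absent")
  expect_lte(sum(ts$raw), lib$library_size)
})

test_that("binned coverage tiles chromosomes and scales to CPM per bin", {
  sizes <- c("A" = 45000L)
  frags <- data.frame(chrom = "A", start = c(100L, 25000L),
                      end = c(300L, 25200L))
  lib <- fragment_library(frags, "wt")
  tr <- binned_coverage(lib, sizes, bin_size = 20000L)
  expect_equal(nrow(tr), 3L)
  expect_equal(tr$start, c(0L, 20000L, 40000L))
  expect_equal(tr$end, c(20000L, 40000L, 45000L))
  expect_equal(tr$raw, c(1L, 1L, 0L))
  expect_equal(tr$score, c(1, 1, 0) * 1e6 / 2)
})

test_that("CPM columns sum to 1e6 when disjoint intervals contain all fragments", {
  set.seed(21)
  # fragments placed fully inside 1-kb tiles so each is counted exactly once
  tile_of <- sample(0:9, 400, replace = TRUE)
  start <- tile_of * 1000L + sample(0:800, 400, replace = TRUE)
  frags <- data.frame(chrom = "2L", start = start,
                      end = start + sample(50:199, 400, replace = TRUE))
  lib <- fragment_library(frags, "wt")
  s <- seq(0L, 9000L, by = 1000L)
  tiles <- data.frame(interval_id = paste0("t", s), chrom = "2L",
                      start = s, end = s + 1000L)
  total_cpm <- sum(cpm(count_overlaps(lib, tiles), lib$library_size))
  expect_equal(total_cpm, 1e6)
})

test_that("log2 bin ratios follow the pseudocounted formula", {
  t1 <- data.frame(chrom = "A", start = c(0L, 10L), end = c(10L, 20L),
                   score = c(4, 2))
  t2 <- data.frame(chrom = "A", start = c(0L, 10L), end = c(10L, 20L),
                   score = c(4, 1))
  expect_equal(log2_bin_ratio(t1, t1, pseudocount = 1)$score, c(0, 0))
  expect_equal(log2_bin_ratio(t1, t2, pseudocount = 0)$score, c(0, 1))
  t3 <- data.frame(chrom = "A", start = 0L, end = 10L, score = 0)
  t4 <- data.frame(chrom = "A", start = 0L, end = 10L, score = 4)
  expect_equal(log2_bin_ratio(t3, t4, pseudocount = 1)$score, log2(1 / 5))
  expect_error(log2_bin_ratio(t1, t3), "mismatch")
})
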