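test_that("parse_gene_models spans transcripts over their features", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    '2L\tsrc\ttranscript\t100\t900\t.\t+\t.\tgene_id "g1"; transcript_id "g1.t1";',
    '2L\tsrc\texon\t100\t900\t.\t+\t.\tgene_id "g1"; transcript_id "g1.t1";',
    # multi-exon '-' transcript: span = min/max over exons
    '2L\tsrc\texon\t1000\t1200\t.\t-\t.\tgene_id "g2"; transcript_id "g2.t1";',
    '2L\tsrc\texon\t1800\t2000\t.\t-\t.\tgene_id "g2"; transcript_id "g2.t1";'
  ), gtf)
  tx <- parse_gene_models(gtf)
  tx <- tx[order(tx$transcript_id), ]
  expect_equal(nrow(tx), 2L)
  expect_equal(tx$start, c(100L, 1000L))
  expect_equal(tx$end, c(900L, 2000L))
  expect_equal(tx$strand, c("+", "-"))
  # agrees with an independent minimal GTF parser on the same file
  oracle <- oracle_parse_gtf(gtf)
  expect_equal(tx$start, oracle$start)
  expect_equal(tx$end, oracle$end)
  expect_equal(tx$gene_id, oracle$gene_id)
})

test_that("parse_gene_models handles empty input and missing gene_id", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(character(0), gtf)
  expect_equal(nrow(parse_gene_models(gtf)), 0L)
  writeLines(
    '2L\tsrc\texon\t100\t900\t.\t+\t.\ttranscript_id "t1";', gtf)
  expect_error(parse_gene_models(gtf), "gene_id")
})

test_that("TSS derivation follows the strand-extreme rule", {
  tx <- tx_df(list("t1", "g1", "2L", 100, 900, "+"),
              list("t2", "g2", "2L", 100, 900, "-"))
  prom <- derive_promoters(tx)
  tab <- promoter_export_table(promoter_windows(
    upstream_promoter_flags(prom), c("2L" = 10000L)))
  expect_equal(tab$tss[tab$gene_id == "g1"], 100L)  # '+': minimum coord
  expect_equal(tab$tss[tab$gene_id == "g2"], 900L)  # '-': maximum coord
})

test_that("duplicate TSSs collapse within genes but not across genes", {
  tx <- tx_df(list("t1", "g1", "2L", 100, 900, "+"),
              list("t2", "g1", "2L", 100, 700, "+"),   # same-gene duplicate
              list("t3", "g2", "2L", 100, 500, "+"),   # cross-gene shared TSS
              list("t4", "g1", "2L", 300, 900, "+"))   # alternative promoter
  prom <- derive_promoters(tx)
  expect_equal(nrow(prom), 3L)
  expect_equal(sum(prom$gene_id == "g1"), 2L)
  expect_equal(sum(prom$gene_id == "g2" & prom$tss == 99L), 1L)
})

test_that("derive_promoters is order-independent", {
  set.seed(7)
  tx <- tx_df(list("t1", "g1", "2L", 100, 900, "+"),
              list("t2", "g1", "2L", 100, 700, "+"),
              list("t3", "g2", "2L", 100, 500, "+"),
              list("t4", "g3", "X", 4000, 6000, "-"),
              list("t5", "g3", "X", 3500, 6000, "-"))
  prom1 <- derive_promoters(tx)
  prom2 <- derive_promoters(tx[sample(nrow(tx)), ])
  expect_identical(prom1, prom2)
})

test_that("promoter windows are strand-oriented, clipped, and bounded", {
  prom <- data.frame(
    promoter_id = c("a", "b", "c"), gene_id = c("a", "b", "c"),
    gene_name = c("a", "b", "c"), chrom = "2L",
    tss = c(1000L, 1000L, 50L), strand = c("+", "-", "+"),
    stringsAsFactors = FALSE)
  w <- promoter_windows(prom, c("2L" = 10000L))
  expect_equal(w$window_start, c(800L, 500L, 0L))
  expect_equal(w$window_end, c(1501L, 1201L, 551L))
  # unoriented mode lays the window left-to-right regardless of strand
  w2 <- promoter_windows(prom, c("2L" = 10000L), oriented = FALSE)
  expect_equal(w2$window_start[2], 800L)
  expect_equal(w2$window_end[2], 1501L)
  # window length == up + down + 1 unless clipped
  expect_equal((w$window_end - w$window_start)[1:2], c(701L, 701L))
  expect_lt((w$window_end - w$window_start)[3], 701L)
  expect_error(promoter_windows(
    data.frame(promoter_id = "z", gene_id = "z", gene_name = "z",
               chrom = "2L", tss = 20000L, strand = "+"),
    c("2L" = 10000L)), "bounds")
})

test_that("upstream flags match the spec examples", {
  prom <- data.frame(
    promoter_id = c("g1", "g2"), gene_id = c("g1", "g2"),
    gene_name = c("g1", "g2"), chrom = "2L",
    tss = c(5000L, 4500L), strand = "+", stringsAsFactors = FALSE)
  f <- upstream_promoter_flags(prom)
  expect_equal(f$upstream_neighbor[1], "g2")
  expect_equal(f$upstream_distance[1], 500L)
  expect_true(f$upstream_within[1])

  # isolated promoter: no neighbor, flag false
  solo <- data.frame(promoter_id = "s", gene_id = "s", gene_name = "s",
                     chrom = "4", tss = 100L, strand = "+",
                     stringsAsFactors = FALSE)
  fs <- upstream_promoter_flags(solo)
  expect_true(is.na(fs$upstream_neighbor))
  expect_false(fs$upstream_within)

  # same-gene alternative TSS 300 bp upstream is excluded; nearest other
  # gene 5 kb away leaves the flag false
  alt <- data.frame(
    promoter_id = c("g1a", "g1b", "g9"), gene_id = c("g1", "g1", "g9"),
    gene_name = c("g1", "g1", "g9"), chrom = "2L",
    tss = c(10000L, 9700L, 5000L), strand = "+", stringsAsFactors = FALSE)
  fa <- upstream_promoter_flags(alt)
  expect_equal(fa$upstream_neighbor[1], "g9")
  expect_equal(fa$upstream_distance[1], 5000L)
  expect_false(fa$upstream_within[1])
})

test_that("upstream flags agree with brute force on random promoter sets", {
  for (s in 1:5) {
    set.seed(s)
    n <- 150
    prom <- data.frame(
      promoter_id = sprintf("p%03d", 1:n),
      gene_id = sprintf("g%03d", sample(60, n, replace = TRUE)),
      gene_name = "x",
      chrom = sample(c("2L", "X"), n, replace = TRUE),
      tss = as.integer(sample(1:20000, n, replace = TRUE)),
      strand = sample(c("+", "-"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    got <- upstream_promoter_flags(prom)
    want <- oracle_upstream(prom)
    expect_equal(got$upstream_neighbor, want$neighbor)
    expect_equal(got$upstream_distance, want$distance)
    expect_equal(got$upstream_within, want$within)
  }
})

test_that("chromosome classification covers both naming dialects", {
  expect_equal(
    as.character(classify_chromosome(
      c("2L", "chr3R", "4", "X", "chrY", "FBte0000123_consensus",
        "mitochondrion_genome"))),
    c("major_autosome", "major_autosome", "fourth", "sex_X", "sex_Y",
      "other", "other"))
})

test_that("gene spans take the union over isoforms", {
  tx <- tx_df(list("t1", "g1", "2L", 100, 900, "+"),
              list("t2", "g1", "2L", 300, 1200, "+"))
  sp <- gene_spans(tx)
  expect_equal(sp$start, 99L)   # 0-based
  expect_equal(sp$end, 1200L)
  expect_equal(sp$length_bp, 1101L)
})
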