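# In-code fixtures and independent oracles shared across the suite.

# transcript-record builder (1-based inclusive, as parse_gene_models emits)
tx_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(transcript_id = r[[1]], gene_id = r[[2]], gene_name = r[[2]],
               chrom = r[[3]], start = as.integer(r[[4]]),
               end = as.integer(r[[5]]), strand = r[[6]],
               stringsAsFactors = FALSE)
  }))
}

# independent minimal GTF parser (no rtracklayer): transcript spans as
# min/max over features sharing a transcript_id
oracle_parse_gtf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  get_attr <- function(a, key) {
    m <- regmatches(a, regexec(paste0(key, ' "([^"]+)"'), a))[[1]]
    if (length(m) == 2L) m[2] else NA_character_
  }
  df <- do.call(rbind, lapply(f, function(x) {
    data.frame(chrom = sub("^chr", "", x[1]), start = as.integer(x[4]),
               end = as.integer(x[5]), strand = x[7],
               transcript_id = get_attr(x[9], "transcript_id"),
               gene_id = get_attr(x[9], "gene_id"), stringsAsFactors = FALSE)
  }))
  df <- df[!is.na(df$transcript_id), ]
  agg <- lapply(split(df, df$transcript_id), function(d) {
    data.frame(transcript_id = d$transcript_id[1], gene_id = d$gene_id[1],
               chrom = d$chrom[1], start = min(d$start), end = max(d$end),
               strand = d$strand[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out[order(out$transcript_id), ]
}

# brute-force all-pairs overlap counter (0-based half-open)
oracle_count_overlaps <- function(fragments, intervals) {
  vapply(seq_len(nrow(intervals)), function(i) {
    sum(fragments$chrom == intervals$chrom[i] &
          fragments$start < intervals$end[i] &
          intervals$start[i] < fragments$end)
  }, 0L)
}

# brute-force nearest upstream promoter of a different gene
oracle_upstream <- function(promoters, max_dist = 1000L) {
  n <- nrow(promoters)
  neighbor <- rep(NA_character_, n)
  distance <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    best_d <- Inf; best_g <- NA_character_
    for (j in seq_len(n)) {
      if (promoters$gene_id[j] == promoters$gene_id[i]) next
      if (promoters$chrom[j] != promoters$chrom[i]) next
      d <- promoters$tss[j] - promoters$tss[i]
      upstream <- if (promoters$strand[i] == "+") d <= 0 else d >= 0
      if (!upstream) next
      if (abs(d) < best_d ||
          (abs(d) == best_d && promoters$gene_id[j] < best_g)) {
        best_d <- abs(d); best_g <- promoters$gene_id[j]
      }
    }
    if (is.finite(best_d)) {
      neighbor[i] <- best_g
      distance[i] <- as.integer(best_d)
    }
  }
  list(neighbor = neighbor, distance = distance,
       within = !is.na(distance) & distance <= max_dist)
}

# adjusted Rand index from the contingency-table closed form
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) sum(choose(x, 2))
  sij <- comb2(tab)
  si <- comb2(rowSums(tab))
  sj <- comb2(colSums(tab))
  n2 <- choose(sum(tab), 2)
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

# tiny two-chromosome world used by several quant tests
tiny_sizes <- c("2L" = 10000L, "X" = 8000L)

random_fragments <- function(n, sizes = tiny_sizes) {
  chrom <- sample(names(sizes), n, replace = TRUE)
  start <- floor(runif(n) * (sizes[chrom] - 300))
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start + sample(50:300, n, replace = TRUE)),
             stringsAsFactors = FALSE)
}

random_intervals <- function(m, sizes = tiny_sizes) {
  chrom <- sample(names(sizes), m, replace = TRUE)
  start <- floor(runif(m) * (sizes[chrom] - 1000))
  data.frame(interval_id = sprintf("iv%03d", seq_len(m)), chrom = chrom,
             start = as.integer(start),
             end = as.integer(start + sample(100:1000, m, replace = TRUE)),
             stringsAsFactors = FALSE)
}
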