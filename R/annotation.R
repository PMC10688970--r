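## Gene-model annotation: transcript spans, TSS-derived promoter tables,
## scoring windows and chromosome classification.
##
## Coordinate convention: GTF is parsed as 1-based inclusive and converted
## ONCE to 0-based half-open at the promoter/window level; every interval
## the quantification layer sees is 0-based half-open (BED-like).

#' Normalize chromosome names
#'
#' Strips a leading "chr" prefix so FlyBase ("2L") and UCSC ("chr2L")
#' dialects compare equal.
#'
#' @param x character vector of chromosome names.
#' @return character vector of bare names.
#' @export
normalize_chrom <- function(x) {
  sub("^chr", "", as.character(x))
}

#' Classify a chromosome name
#'
#' Maps a (normalized) chromosome name to its dosage class: the major
#' autosome arms 2L/2R/3L/3R, the small fourth chromosome, the hemizygous
#' sex chromosomes X and Y, and everything else (transposon consensus
#' scaffolds, mitochondrion, unplaced contigs) as "other".
#'
#' @param name character vector of chromosome names ("2L" or "chr2L" style).
#' @return factor with levels major_autosome, fourth, sex_X, sex_Y, other.
#' @examples
#' classify_chromosome(c("2L", "chr3R", "4", "X", "FBte0000123_consensus"))
#' @export
classify_chromosome <- function(name) {
  bare <- normalize_chrom(name)
  cls <- rep("other", length(bare))
  cls[bare %in% c("2L", "2R", "3L", "3R")] <- "major_autosome"
  cls[bare == "4"] <- "fourth"
  cls[bare == "X"] <- "sex_X"
  cls[bare == "Y"] <- "sex_Y"
  factor(cls, levels = c("major_autosome", "fourth", "sex_X", "sex_Y", "other"))
}

#' Parse gene models from a GTF file
#'
#' Reads a GTF (FlyBase dialect) and returns one record per transcript,
#' with the span taken as the min/max coordinate over all features carrying
#' that transcript_id. Feature lines without a transcript_id (e.g. bare
#' gene lines) are ignored; transcript-level features missing gene_id are a
#' record-level error.
#'
#' @param gtf_file path to a GTF file.
#' @return data.frame with columns transcript_id, gene_id, gene_name,
#'   chrom (normalized), start, end (1-based inclusive, as in GTF), strand.
#' @export
parse_gene_models <- function(gtf_file) {
  empty <- data.frame(transcript_id = character(), gene_id = character(),
                      gene_name = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  if (file.size(gtf_file) == 0) return(empty)
  gr <- rtracklayer::import(gtf_file, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  if (!"transcript_id" %in% colnames(meta)) {
    if (length(gr) == 0L) return(empty)
    stop("GTF has no transcript_id attribute on any feature")
  }
  tx_id <- as.character(meta$transcript_id)
  keep <- !is.na(tx_id) & tx_id != ""
  if (!any(keep)) return(empty)
  gr <- gr[keep]
  meta <- S4Vectors::mcols(gr)
  tx_id <- as.character(meta$transcript_id)
  if (!"gene_id" %in% colnames(meta)) {
    stop("GTF features with transcript_id but missing gene_id")
  }
  gene_id <- as.character(meta$gene_id)
  if (anyNA(gene_id) || any(gene_id == "")) {
    bad <- which(is.na(gene_id) | gene_id == "")
    stop("GTF features with transcript_id but missing gene_id: records ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "")
  }
  gene_name <- if ("gene_symbol" %in% colnames(meta)) {
    as.character(meta$gene_symbol)
  } else if ("gene_name" %in% colnames(meta)) {
    as.character(meta$gene_name)
  } else gene_id
  gene_name[is.na(gene_name)] <- gene_id[is.na(gene_name)]

  dt <- data.table::data.table(
    transcript_id = tx_id,
    gene_id = gene_id,
    gene_name = gene_name,
    chrom = normalize_chrom(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  if (any(dt$strand == "*")) {
    stop("transcript feature(s) with no strand: ",
         paste(unique(dt$transcript_id[dt$strand == "*"])[1:3], collapse = ", "))
  }
  spans <- dt[, list(
    gene_id = gene_id[1L],
    gene_name = gene_name[1L],
    chrom = chrom[1L],
    start = min(start),
    end = max(end),
    strand = strand[1L]
  ), by = "transcript_id"]
  data.table::setDF(spans)
  spans
}

#' Derive a promoter (TSS) table from transcript records
#'
#' The TSS of a '+' transcript is its minimum coordinate and of a '-'
#' transcript its maximum coordinate. Duplicate TSSs within one gene are
#' collapsed (keeping the record from the lexicographically smallest
#' transcript_id); a coordinate shared by two distinct genes yields one
#' promoter record per gene.
#'
#' @param transcripts data.frame as returned by [parse_gene_models()]
#'   (1-based inclusive coordinates).
#' @return data.frame with columns promoter_id, gene_id, gene_name, chrom,
#'   tss (0-based), strand, sorted by (chrom, tss, gene_id).
#' @export
derive_promoters <- function(transcripts) {
  stopifnot(nrow(transcripts) > 0L)
  dt <- data.table::as.data.table(transcripts)
  dt[, tss := ifelse(strand == "+", start, end) - 1L]  # to 0-based
  data.table::setorder(dt, chrom, tss, gene_id, transcript_id)
  prom <- dt[, utils::head(.SD, 1L), by = c("gene_id", "chrom", "tss", "strand")]
  prom <- prom[, c("gene_id", "gene_name", "chrom", "tss", "strand"), with = FALSE]
  data.table::setorder(prom, chrom, tss, gene_id)
  prom[, promoter_id := paste(gene_id, chrom, tss + 1L, strand, sep = ":")]
  data.table::setcolorder(prom, "promoter_id")
  data.table::setDF(prom)
  prom
}

#' Build strand-oriented promoter scoring windows
#'
#' Places a window from `up` bp upstream through `down` bp downstream of
#' each TSS (inclusive of the TSS itself: up + down + 1 positions when
#' unclipped), oriented by strand and clipped to the chromosome. With
#' `oriented = FALSE` the window is laid left-to-right regardless of
#' strand.
#'
#' @param promoters promoter table from [derive_promoters()].
#' @param up,down distances in bp (defaults 200 and 500).
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param oriented mirror the window on '-' strand promoters (default TRUE).
#' @return the promoter table with window_start, window_end
#'   (0-based half-open) appended.
#' @export
promoter_windows <- function(promoters, chrom_sizes, up = 200L, down = 500L,
                             oriented = TRUE) {
  chrom_len <- unname(chrom_sizes[normalize_chrom(promoters$chrom)])
  if (anyNA(chrom_len)) {
    stop("promoters on chromosomes absent from chrom_sizes: ",
         paste(unique(promoters$chrom[is.na(chrom_len)]), collapse = ", "))
  }
  tss <- promoters$tss
  if (any(tss < 0L | tss >= chrom_len)) {
    stop("TSS outside chromosome bounds for promoter(s): ",
         paste(utils::head(promoters$promoter_id[tss < 0L | tss >= chrom_len], 5L),
               collapse = ", "))
  }
  minus <- oriented & promoters$strand == "-"
  ws <- ifelse(minus, tss - down, tss - up)
  we <- ifelse(minus, tss + up + 1L, tss + down + 1L)
  promoters$window_start <- pmax(0L, as.integer(ws))
  promoters$window_end <- pmin(as.integer(chrom_len), as.integer(we))
  promoters
}

#' Nearest upstream promoter of a different gene
#'
#' For each promoter, finds the closest promoter of a *different* gene
#' lying 5' of it in its own orientation (the neighbor's strand is
#' ignored), with ties at equal distance broken by the smaller gene_id.
#' Promoters sharing the exact TSS coordinate are upstream at distance 0.
#'
#' @param promoters promoter table from [derive_promoters()].
#' @param max_dist distance (bp) for the within flag (default 1000).
#' @return the promoter table with upstream_neighbor (gene_id or NA),
#'   upstream_distance (bp, NA if no qualifying neighbor) and
#'   upstream_within (logical) appended.
#' @export
upstream_promoter_flags <- function(promoters, max_dist = 1000L) {
  n <- nrow(promoters)
  neighbor <- rep(NA_character_, n)
  distance <- rep(NA_integer_, n)
  for (ch in unique(promoters$chrom)) {
    idx <- which(promoters$chrom == ch)
    tss <- promoters$tss[idx]
    gid <- promoters$gene_id[idx]
    str <- promoters$strand[idx]
    for (j in seq_along(idx)) {
      up5 <- if (str[j] == "+") tss <= tss[j] else tss >= tss[j]
      cand <- which(up5 & gid != gid[j])
      if (length(cand) == 0L) next
      d <- abs(tss[cand] - tss[j])
      best <- cand[order(d, gid[cand])][1L]
      neighbor[idx[j]] <- gid[best]
      distance[idx[j]] <- abs(tss[best] - tss[j])
    }
  }
  promoters$upstream_neighbor <- neighbor
  promoters$upstream_distance <- distance
  promoters$upstream_within <- !is.na(distance) & distance <= max_dist
  promoters
}

#' Union gene spans for gene-body scoring
#'
#' Collapses transcripts to one interval per gene: min start to max end
#' over the gene's transcripts (multi-isoform handling is not otherwise
#' defined for whole-gene scoring).
#'
#' @param transcripts data.frame from [parse_gene_models()].
#' @return data.frame with gene_id, gene_name, chrom, start (0-based),
#'   end (half-open), strand, length_bp.
#' @export
gene_spans <- function(transcripts) {
  dt <- data.table::as.data.table(transcripts)
  spans <- dt[, list(
    gene_name = gene_name[1L],
    chrom = chrom[1L],
    start = min(start) - 1L,   # to 0-based half-open
    end = max(end),
    strand = strand[1L]
  ), by = "gene_id"]
  spans[, length_bp := end - start]
  data.table::setorder(spans, chrom, start, gene_id)
  data.table::setDF(spans)
  spans
}

#' Assemble the exported promoter table
#'
#' Joins windows and upstream-neighbor annotation into the table written
#' to disk; tss is reported 1-based for human consumption while window
#' coordinates stay 0-based half-open.
#'
#' @param promoters promoter table carrying window and upstream columns.
#' @return data.frame ready for [data.table::fwrite()].
#' @export
promoter_export_table <- function(promoters) {
  data.frame(
    gene_id = promoters$gene_id,
    gene_name = promoters$gene_name,
    chrom = promoters$chrom,
    tss = promoters$tss + 1L,
    strand = promoters$strand,
    window_start = promoters$window_start,
    window_end = promoters$window_end,
    upstream_neighbor = promoters$upstream_neighbor,
    upstream_distance = promoters$upstream_distance,
    upstream_within_1kb = promoters$upstream_within,
    stringsAsFactors = FALSE
  )
}
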