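## Fragment quantification: overlap counting over arbitrary interval sets,
## CPM/CPKM scaling, cross-genotype z-scores, binned coverage tracks and
## log2 bin ratios. All intervals are 0-based half-open; a fragment counts
## once for every interval it overlaps by >= 1 bp.

#' Construct a fragment library
#'
#' @param fragments data.frame with chrom, start, end (0-based half-open).
#' @param label library label (condition / genotype name).
#' @param library_size total mapped fragment count; defaults to
#'   `nrow(fragments)`.
#' @return a FragmentLibrary object.
#' @export
fragment_library <- function(fragments, label, library_size = nrow(fragments)) {
  stopifnot(all(c("chrom", "start", "end") %in% names(fragments)))
  structure(
    list(label = label,
         fragments = data.frame(chrom = normalize_chrom(fragments$chrom),
                                start = as.integer(fragments$start),
                                end = as.integer(fragments$end),
                                stringsAsFactors = FALSE),
         library_size = as.numeric(library_size),
         n_rejected = 0L),
    class = "FragmentLibrary")
}

#' @export
print.FragmentLibrary <- function(x, ...) {
  cat(sprintf("FragmentLibrary '%s': %d fragments (library size %g, %d rejected)\n",
              x$label, nrow(x$fragments), x$library_size, x$n_rejected))
  invisible(x)
}

#' Load a fragment library from a BED3+ file
#'
#' Reads mapped fragment intervals (BED: 0-based half-open). Records on
#' unknown chromosomes or extending beyond the chromosome end are rejected
#' and counted, not silently dropped; malformed coordinate fields are an
#' error naming the offending line.
#'
#' @param path BED3+ file.
#' @param label library label.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @return a FragmentLibrary; `library_size` is the retained record count
#'   and `n_rejected` the number of out-of-bounds records.
#' @export
load_fragments <- function(path, label, chrom_sizes) {
  empty_lib <- fragment_library(
    data.frame(chrom = character(), start = integer(), end = integer()),
    label, 0)
  if (file.size(path) == 0) return(empty_lib)
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (nrow(dt) == 0L) return(empty_lib)
  if (ncol(dt) < 3L) stop("BED file ", path, " has fewer than 3 columns")
  chrom <- normalize_chrom(dt[[1L]])
  start <- suppressWarnings(as.integer(dt[[2L]]))
  end <- suppressWarnings(as.integer(dt[[3L]]))
  bad <- which(is.na(start) | is.na(end) | start < 0L | start >= end)
  if (length(bad) > 0L) {
    stop("malformed BED record(s) in ", path, " at line(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  len <- unname(chrom_sizes[chrom])
  oob <- is.na(len) | end > len
  if (any(oob)) {
    message(sum(oob), " fragment(s) outside chromosome bounds rejected from ",
            label)
  }
  keep <- !oob
  lib <- fragment_library(
    data.frame(chrom = chrom[keep], start = start[keep], end = end[keep],
               stringsAsFactors = FALSE),
    label, sum(keep))
  lib$n_rejected <- sum(oob)
  lib
}

as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
}

#' Count fragments overlapping intervals
#'
#' Half-open overlap test: a fragment is counted once per interval it
#' overlaps by at least 1 bp, and contributes to every interval it
#' overlaps (no assignment to a unique best interval).
#'
#' @param lib a FragmentLibrary.
#' @param intervals data.frame with chrom, start, end (0-based half-open).
#' @return integer vector of raw counts, one per interval row.
#' @export
count_overlaps <- function(lib, intervals) {
  if (nrow(lib$fragments) == 0L) return(integer(nrow(intervals)))
  GenomicRanges::countOverlaps(as_granges(intervals),
                               as_granges(lib$fragments),
                               minoverlap = 1L)
}

#' Counts per million
#'
#' cpm = counts * 1e6 / library size.
#'
#' @param raw raw counts.
#' @param library_size total mapped fragments (> 0).
#' @return numeric vector.
#' @export
cpm <- function(raw, library_size) {
  if (length(library_size) != 1L || library_size <= 0) {
    stop("library_size must be a single positive number")
  }
  raw * 1e6 / library_size
}

#' Counts per kilobase per million
#'
#' cpkm = counts * 1e6 / (library size * interval length in kb).
#'
#' @param raw raw counts.
#' @param library_size total mapped fragments (> 0).
#' @param length_bp interval length(s) in bp (> 0).
#' @return numeric vector.
#' @export
cpkm <- function(raw, library_size, length_bp) {
  if (any(length_bp <= 0)) stop("interval length must be positive")
  cpm(raw, library_size) / (length_bp / 1000)
}

#' Z-scores across a genotype triple
#'
#' Per interval, z_i = (x_i - mean) / sd over the designated libraries,
#' with the population SD (divide by n); zero-variance rows get all-zero
#' z-scores.
#'
#' @param cpm_matrix numeric matrix, intervals x libraries, with library
#'   labels as column names.
#' @param triple character vector of library labels (default the
#'   bam / aly / wildtype genotype series).
#' @return numeric matrix, intervals x length(triple), columns named
#'   `z_<label>`.
#' @export
genotype_zscores <- function(cpm_matrix, triple = c("bam", "aly", "wildtype")) {
  missing_lab <- setdiff(triple, colnames(cpm_matrix))
  if (length(missing_lab) > 0L) {
    stop("libraries missing from score table: ",
         paste(missing_lab, collapse = ", "))
  }
  x <- cpm_matrix[, triple, drop = FALSE]
  mu <- rowMeans(x)
  sdev <- sqrt(rowMeans((x - mu)^2))
  z <- (x - mu) / ifelse(sdev > 0, sdev, 1)
  z[sdev == 0, ] <- 0
  colnames(z) <- paste0("z_", triple)
  z
}

#' Score an interval set across fragment libraries
#'
#' Builds the interval x library table of raw counts, CPM and CPKM used
#' for promoter, gene-body and transposon scoring.
#'
#' @param libs list of FragmentLibrary objects.
#' @param intervals data.frame with interval_id, chrom, start, end.
#' @return data.frame: interval_id, chrom, start, end, length_bp, then
#'   raw_/cpm_/cpkm_ columns per library label.
#' @export
score_table <- function(libs, intervals) {
  out <- data.frame(interval_id = intervals$interval_id,
                    chrom = intervals$chrom,
                    start = intervals$start,
                    end = intervals$end,
                    length_bp = intervals$end - intervals$start,
                    stringsAsFactors = FALSE)
  for (lib in libs) {
    raw <- count_overlaps(lib, intervals)
    out[[paste0("raw_", lib$label)]] <- raw
    out[[paste0("cpm_", lib$label)]] <- cpm(raw, lib$library_size)
    out[[paste0("cpkm_", lib$label)]] <- cpkm(raw, lib$library_size,
                                              out$length_bp)
  }
  out
}

#' Score transposon consensus scaffolds
#'
#' Each consensus sequence is scored as a single full-length interval and
#' scaled as CPKM.
#'
#' @param lib a FragmentLibrary.
#' @param consensus_lengths named integer vector (id -> length in bp).
#' @param chrom_sizes chromosome length table the library was loaded
#'   against; every consensus id must be present.
#' @return data.frame with interval_id, length_bp, raw, cpkm.
#' @export
transposon_scores <- function(lib, consensus_lengths, chrom_sizes) {
  ids <- names(consensus_lengths)
  unknown <- setdiff(ids, names(chrom_sizes))
  if (length(unknown) > 0L) {
    stop("consensus id(s) absent from chrom_sizes: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  intervals <- data.frame(interval_id = ids, chrom = ids, start = 0L,
                          end = as.integer(consensus_lengths),
                          stringsAsFactors = FALSE)
  raw <- count_overlaps(lib, intervals)
  data.frame(interval_id = ids, length_bp = intervals$end,
             raw = raw, cpkm = cpkm(raw, lib$library_size, intervals$end),
             stringsAsFactors = FALSE)
}

#' Binned CPM coverage track
#'
#' Tiles every chromosome from position 0 in consecutive `bin_size`
#' windows (the last bin may be short), counts fragment overlaps per bin,
#' and scales by 1e6 / library size (CPM per bin).
#'
#' @param lib a FragmentLibrary (library_size > 0).
#' @param chrom_sizes named integer vector.
#' @param bin_size bin width in bp (default 20000, the 20-kb display
#'   resolution).
#' @return BinnedTrack data.frame: chrom, start, end, raw, score.
#' @export
binned_coverage <- function(lib, chrom_sizes, bin_size = 20000L) {
  if (lib$library_size <= 0) stop("empty library: no scaling basis")
  if (bin_size <= 0) stop("bin_size must be positive")
  tiles <- GenomicRanges::tileGenome(chrom_sizes, tilewidth = bin_size,
                                     cut.last.tile.in.chrom = TRUE)
  track <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(tiles)),
    start = GenomicRanges::start(tiles) - 1L,
    end = GenomicRanges::end(tiles),
    stringsAsFactors = FALSE)
  track$raw <- count_overlaps(lib, track)
  track$score <- cpm(track$raw, lib$library_size)
  attr(track, "bin_size") <- as.integer(bin_size)
  track
}

#' Log2 ratio of two binned tracks
#'
#' Per bin, log2((a + rho) / (b + rho)); the pseudocount rho keeps empty
#' bins finite.
#'
#' @param track_a,track_b BinnedTrack data.frames on identical binnings.
#' @param pseudocount rho, in the tracks' score units (default 1).
#' @return BinnedTrack data.frame with the log2 ratio in `score`.
#' @export
log2_bin_ratio <- function(track_a, track_b, pseudocount = 1) {
  if (nrow(track_a) != nrow(track_b) ||
      !all(track_a$chrom == track_b$chrom) ||
      !all(track_a$start == track_b$start) ||
      !all(track_a$end == track_b$end)) {
    stop("binning mismatch between tracks")
  }
  out <- track_a[, c("chrom", "start", "end")]
  out$score <- log2((track_a$score + pseudocount) /
                    (track_b$score + pseudocount))
  out
}
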