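## Chromosome-scale dosage statistics. Male flies carry one X and one Y
## but two copies of each autosome (including the fourth chromosome), so
## sex-linked gene scores are doubled to express signal per gene copy,
## then all scores are scaled to the median per-copy score of genes on
## the major autosomes (2L/2R/3L/3R). On that scale, a dosage-compensated
## X has median ~2 and an uncompensated X has median ~1.

#' Per-copy gene scores
#'
#' Doubles scores of genes on the hemizygous sex chromosomes (X and Y);
#' autosomal genes, including the fourth chromosome, are unchanged.
#'
#' @param gene_score numeric vector of gene scores (e.g. CPKM).
#' @param chrom_class factor from [classify_chromosome()], one per gene.
#' @return numeric vector of copy-adjusted scores.
#' @export
per_copy_scores <- function(gene_score, chrom_class) {
  stopifnot(length(gene_score) == length(chrom_class), !anyNA(chrom_class))
  ifelse(chrom_class %in% c("sex_X", "sex_Y"), 2 * gene_score, gene_score)
}

#' Scale scores to the major-autosome median
#'
#' Divides every score by the median per-copy score over major-autosome
#' genes, so the scaled major-autosome median is exactly 1.
#'
#' @param per_copy numeric vector of per-copy scores.
#' @param chrom_class factor from [classify_chromosome()], one per gene.
#' @return numeric vector of scaled scores.
#' @export
scale_to_autosome_median <- function(per_copy, chrom_class) {
  auto <- per_copy[chrom_class == "major_autosome"]
  if (length(auto) == 0L) stop("no major-autosome genes to scale against")
  med <- stats::median(auto)
  if (med <= 0) stop("major-autosome median is not positive; cannot scale")
  per_copy / med
}

#' Filter to genes scored in every condition
#'
#' Keeps genes whose enrichment score is > 0 in every supplied condition
#' (genes silent in any one condition are discarded before the dosage
#' boxplot statistics).
#'
#' @param score_matrix numeric genes x conditions matrix with gene ids as
#'   rownames.
#' @return character vector of retained gene ids.
#' @export
expressed_gene_filter <- function(score_matrix) {
  stopifnot(is.matrix(score_matrix) || is.data.frame(score_matrix))
  m <- as.matrix(score_matrix)
  rownames(m)[apply(m > 0, 1L, all)]
}

#' Per-chromosome-class score summaries
#'
#' Median and quartiles (linear-interpolation, type 7) of scaled scores
#' per chromosome class; classes with no genes are omitted with a note.
#'
#' @param scaled numeric vector of scaled scores.
#' @param chrom_class factor from [classify_chromosome()], one per gene.
#' @return data.frame: chrom_class, n_genes, q1, median, q3.
#' @export
chromosome_summary <- function(scaled, chrom_class) {
  stopifnot(length(scaled) == length(chrom_class))
  out <- list()
  for (cls in levels(chrom_class)) {
    v <- scaled[chrom_class == cls]
    if (length(v) == 0L) {
      message("chromosome class ", cls, " has no genes; omitted")
      next
    }
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    out[[cls]] <- data.frame(chrom_class = cls, n_genes = length(v),
                             q1 = q[1L], median = q[2L], q3 = q[3L],
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Full dosage-scaling pipeline for one condition
#'
#' Applies, in order: the expressed-gene filter (genes with score > 0 in
#' every condition of `filter_matrix`), the hemizygous per-copy doubling,
#' and autosome-median scaling, then summarizes by chromosome class.
#'
#' @param gene_cpkm named numeric vector of gene CPKM for the condition
#'   being summarized.
#' @param chrom_class factor aligned with `gene_cpkm`.
#' @param filter_matrix optional genes x conditions score matrix for the
#'   cross-condition zero filter (rownames = gene ids); NULL disables the
#'   filter.
#' @return list with `genes` (per-gene data.frame: gene_id, chrom_class,
#'   raw_cpkm, per_copy, scaled) and `summary` (per-class data.frame).
#' @export
dosage_statistics <- function(gene_cpkm, chrom_class, filter_matrix = NULL) {
  stopifnot(!is.null(names(gene_cpkm)))
  keep <- names(gene_cpkm)
  if (!is.null(filter_matrix)) {
    keep <- intersect(keep, expressed_gene_filter(filter_matrix))
  }
  sel <- names(gene_cpkm) %in% keep
  score <- gene_cpkm[sel]
  cls <- droplevels_keep(chrom_class[sel])
  pc <- per_copy_scores(score, cls)
  scl <- scale_to_autosome_median(pc, cls)
  list(
    genes = data.frame(gene_id = names(score), chrom_class = cls,
                       raw_cpkm = unname(score), per_copy = unname(pc),
                       scaled = unname(scl), stringsAsFactors = FALSE),
    summary = chromosome_summary(scl, cls))
}

# keep the full level set so empty classes are reported as omitted
droplevels_keep <- function(x) {
  factor(as.character(x),
         levels = c("major_autosome", "fourth", "sex_X", "sex_Y", "other"))
}
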