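## Small-format readers/writers: chrom.sizes, consensus lengths, bedGraph.

#' Read a chrom.sizes table
#'
#' Two-column TSV (name, length); names are normalized to the bare
#' FlyBase dialect.
#'
#' @param path file path.
#' @return named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "length"))
  stats::setNames(as.integer(dt$length), normalize_chrom(dt$chrom))
}

#' Read transposon consensus lengths
#'
#' Two-column TSV (consensus id, length in bp).
#'
#' @param path file path.
#' @return named integer vector.
#' @export
read_consensus_lengths <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("id", "length"))
  stats::setNames(as.integer(dt$length), as.character(dt$id))
}

#' Read a cluster annotation TSV
#'
#' Three columns: cluster_id, role (germline / somatic / unannotated),
#' order_index (developmental order for germline clusters; NA otherwise).
#'
#' @param path file path.
#' @return a [cluster_annotation()].
#' @export
read_cluster_annotation <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  cluster_annotation(dt$cluster_id, dt$role, dt$order_index)
}

#' Read a clusters x genes expression matrix TSV
#'
#' First column: cluster id; remaining columns: one per gene.
#'
#' @param path matrix TSV path.
#' @param annotation a [cluster_annotation()] covering the rows.
#' @return an ExpressionAtlas.
#' @export
read_expression_atlas <- function(path, annotation) {
  mat <- as.matrix(data.table::fread(path, sep = "\t", header = TRUE),
                   rownames = 1)
  expression_atlas(mat, annotation)
}

#' Write an expression atlas to TSV files
#'
#' @param atlas an ExpressionAtlas.
#' @param matrix_path output path for the clusters x genes matrix.
#' @param annotation_path output path for the cluster annotation.
#' @return invisibly, the matrix path.
#' @export
write_expression_atlas <- function(atlas, matrix_path, annotation_path) {
  dt <- data.table::as.data.table(atlas$matrix, keep.rownames = "cluster_id")
  data.table::fwrite(dt, matrix_path, sep = "\t")
  data.table::fwrite(atlas$annotation, annotation_path, sep = "\t")
  invisible(matrix_path)
}

#' Write fragment intervals as BED3
#'
#' Headerless 3-column BED (0-based half-open), the format
#' [load_fragments()] reads back.
#'
#' @param fragments data.frame with chrom, start, end.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_bed <- function(fragments, path) {
  data.table::fwrite(fragments[, c("chrom", "start", "end")], path,
                     sep = "\t", col.names = FALSE, scipen = 50L)
  invisible(path)
}

#' Write a binned track as 4-column bedGraph
#'
#' @param track data.frame with chrom, start, end, score (0-based
#'   half-open).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  data.table::fwrite(track[, c("chrom", "start", "end", "score")], path,
                     sep = "\t", col.names = FALSE, scipen = 50L)
  invisible(path)
}

#' Write a data frame as TSV
#'
#' @param x data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
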