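## End-to-end analyses: promoter staging (annotation + atlas + genotype
## z-scores), chromosome dosage analysis (filter -> per-copy -> scale ->
## summaries + binned log2-ratio track), and track export. Each step
## reports its record counts so the bookkeeping numbers (promoter-table
## size, fragments loaded, genes filtered) are visible in the log.

#' Build a run configuration
#'
#' Defaults are the analysis defaults: a -200..+500 promoter window,
#' 20-kb bins, k = 10 staging clusters, log2 fold-change threshold 1,
#' enrichment pseudocount 0.01, bin-ratio pseudocount 1, the
#' bam / aly / wildtype genotype triple and the spermatocyte-vs-wing
#' condition pair.
#'
#' @param ... overrides for any default field.
#' @return a RunConfig list.
#' @export
run_config <- function(...) {
  cfg <- list(
    window_up = 200L,
    window_down = 500L,
    window_oriented = TRUE,
    upstream_max_dist = 1000L,
    bin_size = 20000L,
    k = 10L,
    kmeans_restarts = 50L,
    enrichment_threshold = 1,
    pseudocount_eps = 0.01,
    pseudocount_rho = 1,
    genotype_triple = c("bam", "aly", "wildtype"),
    condition_pair = c("spermatocyte", "wing"),
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  cfg
}

lib_labels <- function(libs) vapply(libs, function(l) l$label, "")

require_labels <- function(libs, labels) {
  missing_lab <- setdiff(labels, lib_labels(libs))
  if (length(missing_lab) > 0L) {
    stop("configuration error: library label(s) not supplied: ",
         paste(missing_lab, collapse = ", "))
  }
}

#' Promoter scoring and staging analysis
#'
#' Derives the promoter table from transcript models, scores the
#' -200..+500 windows in each genotype library (CPM), computes per-promoter
#' z-scores across the genotype triple, and annotates each promoter's gene
#' with its germline/somatic enrichment and k-means stage from the atlas.
#'
#' @param transcripts data.frame from [parse_gene_models()].
#' @param libs list of FragmentLibrary objects covering the genotype
#'   triple.
#' @param atlas an ExpressionAtlas.
#' @param chrom_sizes named integer vector.
#' @param config a [run_config()].
#' @param out_dir optional output directory for TSVs.
#' @return data.frame: the promoter table with per-genotype cpm, z,
#'   gexp/sexp/log2fc, enriched and stage columns.
#' @export
run_promoter_staging <- function(transcripts, libs, atlas, chrom_sizes,
                                 config = run_config(), out_dir = NULL) {
  require_labels(libs, config$genotype_triple)
  if (nrow(transcripts) == 0L) {
    warning("no transcripts supplied; empty promoter table")
    return(data.frame())
  }
  prom <- derive_promoters(transcripts)
  prom <- promoter_windows(prom, chrom_sizes, up = config$window_up,
                           down = config$window_down,
                           oriented = config$window_oriented)
  prom <- upstream_promoter_flags(prom, max_dist = config$upstream_max_dist)
  message(nrow(prom), " promoters derived from ", nrow(transcripts),
          " transcripts")

  intervals <- data.frame(interval_id = prom$promoter_id, chrom = prom$chrom,
                          start = prom$window_start, end = prom$window_end,
                          stringsAsFactors = FALSE)
  triple_libs <- libs[match(config$genotype_triple, lib_labels(libs))]
  st <- score_table(triple_libs, intervals)
  cpm_mat <- as.matrix(st[, paste0("cpm_", config$genotype_triple)])
  colnames(cpm_mat) <- config$genotype_triple
  z <- genotype_zscores(cpm_mat, config$genotype_triple)

  summ <- germline_somatic_summary(atlas, genes = unique(prom$gene_id),
                                   pseudocount = config$pseudocount_eps)
  enr <- select_germline_enriched(summ, config$enrichment_threshold)
  summ$enriched <- summ$gene_id %in% enr$selected
  message(length(enr$selected), " germline-enriched genes; ",
          length(enr$missing), " genes absent from the atlas")
  stages <- stage_by_kmeans(atlas, genes = unique(prom$gene_id),
                            k = config$k, seed = config$seed,
                            restarts = config$kmeans_restarts)

  out <- cbind(promoter_export_table(prom),
               st[, grep("^(raw|cpm)_", names(st))], z)
  out <- merge(out, summ, by = "gene_id", sort = FALSE)
  out <- merge(out, stages, by = "gene_id", sort = FALSE)
  out <- out[order(out$chrom, out$tss, out$gene_id), ]
  rownames(out) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(out, file.path(out_dir, "promoter_staging.tsv"))
  }
  out
}

#' Chromosome dosage analysis
#'
#' Scores gene bodies (CPKM) in every supplied library, discards genes
#' with a zero score in any library, doubles hemizygous (X/Y) scores to
#' per-copy values, scales to the major-autosome median, and summarizes
#' by chromosome class. Also emits 20-kb binned CPM tracks for the
#' configured condition pair and their log2 ratio.
#'
#' @param transcripts data.frame from [parse_gene_models()].
#' @param libs list of FragmentLibrary objects; the first two labels of
#'   `config$condition_pair` must be present.
#' @param chrom_sizes named integer vector.
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @return list: `genes` (per-condition per-gene tables), `summaries`
#'   (per-condition chromosome-class summaries), `tracks` (binned CPM
#'   per condition), `log2_ratio` (BinnedTrack,
#'   condition_pair[1] vs condition_pair[2]).
#' @export
run_dosage_analysis <- function(transcripts, libs, chrom_sizes,
                                config = run_config(), out_dir = NULL) {
  require_labels(libs, config$condition_pair)
  spans <- gene_spans(transcripts)
  intervals <- data.frame(interval_id = spans$gene_id, chrom = spans$chrom,
                          start = spans$start, end = spans$end,
                          stringsAsFactors = FALSE)
  st <- score_table(libs, intervals)
  labels <- lib_labels(libs)
  cpkm_mat <- as.matrix(st[, paste0("cpkm_", labels)])
  dimnames(cpkm_mat) <- list(st$interval_id, labels)
  cls <- classify_chromosome(spans$chrom)

  kept <- expressed_gene_filter(cpkm_mat)
  message(length(kept), " of ", nrow(cpkm_mat),
          " genes scored > 0 in every library")

  genes_out <- list(); summaries <- list()
  for (lab in labels) {
    ds <- dosage_statistics(
      stats::setNames(cpkm_mat[, lab], rownames(cpkm_mat)), cls,
      filter_matrix = cpkm_mat)
    genes_out[[lab]] <- ds$genes
    summaries[[lab]] <- ds$summary
  }

  pair <- config$condition_pair
  pair_libs <- libs[match(pair, labels)]
  tracks <- lapply(pair_libs, binned_coverage, chrom_sizes = chrom_sizes,
                   bin_size = config$bin_size)
  names(tracks) <- pair
  ratio <- log2_bin_ratio(tracks[[pair[1L]]], tracks[[pair[2L]]],
                          pseudocount = config$pseudocount_rho)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (lab in labels) {
      write_tsv(genes_out[[lab]],
                file.path(out_dir, paste0("dosage_genes_", lab, ".tsv")))
      write_tsv(summaries[[lab]],
                file.path(out_dir, paste0("dosage_summary_", lab, ".tsv")))
    }
    for (lab in pair) {
      write_bedgraph(tracks[[lab]],
                     file.path(out_dir, paste0("coverage_", lab, ".bedgraph")))
    }
    write_bedgraph(ratio, file.path(out_dir, paste0(
      "log2_", pair[1L], "_vs_", pair[2L], ".bedgraph")))
  }
  list(genes = genes_out, summaries = summaries, tracks = tracks,
       log2_ratio = ratio)
}

#' Export binned coverage tracks
#'
#' One CPM-scaled bedGraph per library, bins tiling every chromosome.
#'
#' @param libs list of FragmentLibrary objects.
#' @param chrom_sizes named integer vector.
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return named list of BinnedTrack data.frames, invisibly if written.
#' @export
run_track_export <- function(libs, chrom_sizes, config = run_config(),
                             out_dir = NULL) {
  tracks <- lapply(libs, binned_coverage, chrom_sizes = chrom_sizes,
                   bin_size = config$bin_size)
  names(tracks) <- lib_labels(libs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (lab in names(tracks)) {
      write_bedgraph(tracks[[lab]],
                     file.path(out_dir, paste0("coverage_", lab, ".bedgraph")))
    }
    return(invisible(tracks))
  }
  tracks
}

#' Bookkeeping report for an annotation + atlas pairing
#'
#' The deterministic census of a promoter-table build: promoter count,
#' number of TSS coordinates shared by two or more distinct genes, genes
#' absent from the expression atlas, germline-enriched gene count, and
#' the atlas dimensions. On the real FlyBase r6.31 + testis-atlas inputs
#' these are exact release-level constants; on synthetic inputs they
#' describe the simulated world.
#'
#' @param transcripts data.frame from [parse_gene_models()].
#' @param atlas an ExpressionAtlas.
#' @param threshold log2 fold-change threshold for enrichment (default 1).
#' @param pseudocount enrichment pseudocount (default 0.01).
#' @return list: n_promoters, n_shared_tss, n_missing_genes, n_enriched,
#'   atlas_dim (clusters, genes).
#' @export
bookkeeping_report <- function(transcripts, atlas, threshold = 1,
                               pseudocount = 0.01) {
  prom <- derive_promoters(transcripts)
  coord <- paste(prom$chrom, prom$tss)
  shared <- tapply(prom$gene_id, coord, function(g) length(unique(g)) >= 2L)
  summ <- germline_somatic_summary(atlas, genes = unique(prom$gene_id),
                                   pseudocount = pseudocount)
  enr <- select_germline_enriched(summ, threshold)
  list(n_promoters = nrow(prom),
       n_shared_tss = sum(shared),
       n_missing_genes = length(enr$missing),
       n_enriched = length(enr$selected),
       atlas_dim = dim(atlas$matrix))
}
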