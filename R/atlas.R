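## Expression-atlas processing: cluster-average expression, germline vs
## somatic enrichment summaries, k-means developmental staging and
## germline-cluster z-score profiles.
##
## The atlas emulates a testis single-nucleus clustering: 40 cell-type
## clusters of which 18 are germline (in developmental order,
## spermatogonium -> spermatid), 21 somatic, and 1 unannotated; the
## unannotated cluster is excluded from all summaries.

#' Construct a cluster annotation
#'
#' @param cluster_id character vector of unique cluster ids.
#' @param role one of germline / somatic / unannotated per cluster.
#' @param order_index developmental order for germline clusters (NA for
#'   others); defaults to the germline clusters' input order.
#' @return data.frame with class "ClusterAnnotation".
#' @export
cluster_annotation <- function(cluster_id, role, order_index = NULL) {
  stopifnot(!anyDuplicated(cluster_id),
            all(role %in% c("germline", "somatic", "unannotated")))
  if (is.null(order_index)) {
    order_index <- rep(NA_integer_, length(cluster_id))
    order_index[role == "germline"] <- seq_len(sum(role == "germline"))
  }
  ann <- data.frame(cluster_id = as.character(cluster_id), role = role,
                    order_index = as.integer(order_index),
                    stringsAsFactors = FALSE)
  class(ann) <- c("ClusterAnnotation", "data.frame")
  ann
}

#' Construct an expression atlas
#'
#' @param mat clusters x genes matrix of non-negative mean expression,
#'   with cluster ids as rownames and gene ids as colnames.
#' @param annotation a [cluster_annotation()] covering every matrix row.
#' @return an ExpressionAtlas object.
#' @export
expression_atlas <- function(mat, annotation) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)),
            all(rownames(mat) %in% annotation$cluster_id),
            !anyDuplicated(colnames(mat)))
  if (any(mat < 0)) stop("expression atlas has negative entries")
  ann <- annotation[match(rownames(mat), annotation$cluster_id), ]
  structure(list(matrix = mat, annotation = ann), class = "ExpressionAtlas")
}

#' @export
print.ExpressionAtlas <- function(x, ...) {
  tab <- table(x$annotation$role)
  cat(sprintf("ExpressionAtlas: %d clusters (%s) x %d genes\n",
              nrow(x$matrix),
              paste(names(tab), tab, sep = "=", collapse = ", "),
              ncol(x$matrix)))
  invisible(x)
}

#' Average a cells x genes matrix into clusters
#'
#' Entry (c, g) is the arithmetic mean of the (already normalized)
#' expression of gene g over the cells labeled c; the normalization of
#' the input matrix is the caller's responsibility.
#'
#' @param cell_matrix numeric cells x genes matrix.
#' @param labels cluster label per cell (row).
#' @param annotation a [cluster_annotation()]; every annotated cluster
#'   must have at least one cell.
#' @return an ExpressionAtlas.
#' @export
cluster_means <- function(cell_matrix, labels, annotation) {
  stopifnot(nrow(cell_matrix) == length(labels))
  empty <- setdiff(annotation$cluster_id, unique(as.character(labels)))
  if (length(empty) > 0L) {
    stop("cluster(s) with no cells: ", paste(empty, collapse = ", "))
  }
  sums <- rowsum(cell_matrix, group = as.character(labels))
  means <- sums / as.vector(table(as.character(labels))[rownames(sums)])
  expression_atlas(means[annotation$cluster_id, , drop = FALSE], annotation)
}

#' Germline / somatic expression summary per gene
#'
#' gexp is the mean expression over germline clusters, sexp over somatic
#' clusters (the unannotated cluster enters neither), and
#' log2fc = log2((gexp + eps) / (sexp + eps)). Genes requested but absent
#' from the atlas are reported with NA values (the missing marker).
#'
#' @param atlas an ExpressionAtlas.
#' @param genes gene universe to report (default: all atlas genes).
#' @param pseudocount eps added to both means before the ratio
#'   (default 0.01); keeps the ratio finite when sexp = 0.
#' @return data.frame: gene_id, gexp, sexp, log2fc, missing.
#' @export
germline_somatic_summary <- function(atlas, genes = colnames(atlas$matrix),
                                     pseudocount = 0.01) {
  ann <- atlas$annotation
  g_rows <- ann$cluster_id[ann$role == "germline"]
  s_rows <- ann$cluster_id[ann$role == "somatic"]
  stopifnot(length(g_rows) >= 1L, length(s_rows) >= 1L)
  gexp_all <- colMeans(atlas$matrix[g_rows, , drop = FALSE])
  sexp_all <- colMeans(atlas$matrix[s_rows, , drop = FALSE])
  idx <- match(genes, colnames(atlas$matrix))
  gexp <- gexp_all[idx]
  sexp <- sexp_all[idx]
  data.frame(
    gene_id = genes,
    gexp = unname(gexp),
    sexp = unname(sexp),
    log2fc = unname(log2((gexp + pseudocount) / (sexp + pseudocount))),
    missing = is.na(idx),
    stringsAsFactors = FALSE)
}

#' Select germline-enriched genes
#'
#' Keeps genes with log2 fold-change >= threshold (inclusive) and
#' non-missing expression; genes absent from the atlas are returned
#' separately.
#'
#' @param summaries output of [germline_somatic_summary()].
#' @param threshold log2 fold-change cutoff (default 1).
#' @return list with `selected` and `missing` gene-id vectors.
#' @export
select_germline_enriched <- function(summaries, threshold = 1) {
  sel <- !summaries$missing & !is.na(summaries$log2fc) &
    summaries$log2fc >= threshold
  list(selected = summaries$gene_id[sel],
       missing = summaries$gene_id[summaries$missing])
}

row_zscore <- function(x) {
  mu <- rowMeans(x)
  sdev <- sqrt(rowMeans((x - mu)^2))
  z <- (x - mu) / ifelse(sdev > 0, sdev, 1)
  z[sdev == 0, ] <- 0
  z
}

#' Stage genes by k-means over cell-type expression profiles
#'
#' Rows are per-gene expression profiles over the annotated clusters
#' (germline + somatic; the unannotated cluster is excluded), z-scored per
#' gene so profile shape rather than absolute level drives the clustering.
#' Each k-cluster is called germline- or somatic-associated by where its
#' centroid mass lies; somatic-associated clusters collapse into the
#' single group "11" and germline-associated groups are renumbered 1..n
#' by the position of their centroid peak along the germline
#' developmental order. Genes absent from the atlas are "unassigned".
#'
#' @param atlas an ExpressionAtlas.
#' @param genes genes to stage.
#' @param k number of k-means clusters (default 10).
#' @param seed RNG seed for initialization.
#' @param restarts k-means restarts (default 50).
#' @param feature_space "annotated" (germline + somatic clusters, the
#'   default) or "germline" (germline clusters only).
#' @return data.frame: gene_id, kcluster (raw k-means label, NA when
#'   unassigned), stage (character: "1".."n", "11", or "unassigned").
#' @export
stage_by_kmeans <- function(atlas, genes, k = 10L, seed = 1L, restarts = 50L,
                            feature_space = c("annotated", "germline")) {
  feature_space <- match.arg(feature_space)
  ann <- atlas$annotation
  roles_used <- if (feature_space == "annotated") c("germline", "somatic")
                else "germline"
  cl_use <- ann[ann$role %in% roles_used, ]
  cl_use <- cl_use[order(cl_use$role != "germline", cl_use$order_index), ]
  present <- genes[genes %in% colnames(atlas$matrix)]
  if (length(present) < k) {
    stop("fewer genes (", length(present), ") than clusters k = ", k)
  }
  x <- t(atlas$matrix[cl_use$cluster_id, present, drop = FALSE])
  x <- row_zscore(x)

  n_distinct <- nrow(unique(x))
  k_eff <- min(k, n_distinct)
  if (k_eff < k) {
    warning("only ", n_distinct, " distinct profiles; ", k - k_eff,
            " of ", k, " clusters left empty")
  }
  set.seed(seed)
  km <- stats::kmeans(x, centers = k_eff, nstart = restarts, iter.max = 100L)

  is_germ_col <- cl_use$role == "germline"
  germ_order <- order(cl_use$order_index[is_germ_col])
  centers <- km$centers
  germ_mass <- rowMeans(centers[, is_germ_col, drop = FALSE])
  som_mass <- if (any(!is_germ_col)) {
    rowMeans(centers[, !is_germ_col, drop = FALSE])
  } else rep(-Inf, nrow(centers))
  germ_assoc <- germ_mass > som_mass
  peak <- apply(centers[, which(is_germ_col)[germ_order], drop = FALSE],
                1L, which.max)

  # germline-associated clusters are numbered by centroid peak position
  # along the germline developmental order; clusters peaking at the same
  # position share a stage label (k > n_archetypes splits clusters by
  # noise, not shape, so coincident peaks mark one stage)
  stage_of <- rep("11", k_eff)
  g_idx <- which(germ_assoc)
  peaks <- sort(unique(peak[g_idx]))
  stage_of[g_idx] <- as.character(match(peak[g_idx], peaks))

  out <- data.frame(gene_id = genes,
                    kcluster = NA_integer_,
                    stage = "unassigned",
                    stringsAsFactors = FALSE)
  m <- match(present, genes)
  out$kcluster[m] <- unname(km$cluster)
  out$stage[m] <- stage_of[km$cluster]
  out
}

#' Z-score expression profiles over germline clusters
#'
#' Per gene, z-scores across its germline-cluster values (population SD;
#' constant rows give all-zero z), columns ordered by the germline
#' developmental order.
#'
#' @param atlas an ExpressionAtlas with >= 2 germline clusters.
#' @param genes genes to include (must be present in the atlas).
#' @return genes x germline-clusters numeric matrix.
#' @export
germline_cluster_zscores <- function(atlas, genes = colnames(atlas$matrix)) {
  ann <- atlas$annotation
  germ <- ann[ann$role == "germline", ]
  stopifnot(nrow(germ) >= 2L)
  germ <- germ[order(germ$order_index), ]
  missing <- setdiff(genes, colnames(atlas$matrix))
  if (length(missing) > 0L) {
    stop("gene(s) absent from atlas: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  x <- t(atlas$matrix[germ$cluster_id, genes, drop = FALSE])
  row_zscore(x)
}
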