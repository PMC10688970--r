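#!/usr/bin/env Rscript
# Step 2: promoter table, genotype z-scores and developmental staging.
#
# Derives the strand-aware TSS table from the gene models, scores the
# -200..+500 promoter windows in the bam / aly / wildtype libraries
# (CPM), computes per-promoter z-scores across the genotype triple, and
# annotates every gene with its germline/somatic enrichment and k-means
# stage from the expression atlas. Writes the combined table and the
# germline-cluster z-score matrix under results/promoter_staging/.

suppressMessages(library(germchrom))

data_dir <- "results/data"
out <- "results/promoter_staging"
chrom_sizes <- read_chrom_sizes(file.path(data_dir, "chrom.sizes"))
tx <- parse_gene_models(file.path(data_dir, "synthetic_genes.gtf"))
libs <- lapply(c("bam", "aly", "wildtype"), function(lab) {
  load_fragments(file.path(data_dir, paste0("fragments_", lab, ".bed")),
                 lab, chrom_sizes)
})
atlas <- read_expression_atlas(
  file.path(data_dir, "atlas_matrix.tsv"),
  read_cluster_annotation(file.path(data_dir, "atlas_clusters.tsv")))

cfg <- run_config(seed = 20260918L)
tab <- run_promoter_staging(tx, libs, atlas, chrom_sizes, cfg, out)
message("stage distribution over promoters:")
print(table(tab$stage))

enriched <- unique(tab$gene_id[tab$enriched])
z <- germline_cluster_zscores(atlas, enriched)
write_tsv(data.table::as.data.table(z, keep.rownames = "gene_id"),
          file.path(out, "germline_zscores.tsv"))
message(length(enriched), " germline-enriched genes; z-score matrix ",
        "written to ", out)
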