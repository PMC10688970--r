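#!/usr/bin/env Rscript
# Step 1: build the synthetic study inputs.
#
# Emits, under results/data/, everything the downstream steps consume
# through the package's standard-format readers: gene models (GTF), the
# chromosome table, per-condition fragment BEDs (somatic "wing" with a
# compensated X and silent Y; "spermatocyte" with an uncompensated X and
# activated Y; a bam/aly/wildtype genotype trio with promoter-centered
# signal), the 40-cluster expression atlas, transposon consensus lengths,
# and the planted truth.

suppressMessages(library(germchrom))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260918L

cfg <- synthetic_config()
sim <- simulate_annotation(cfg, seed = seed)
writeLines(sim$gtf, file.path(out, "synthetic_genes.gtf"))
data.table::fwrite(data.frame(chrom = names(sim$chrom_sizes),
                              length = unname(sim$chrom_sizes)),
                   file.path(out, "chrom.sizes"),
                   sep = "\t", col.names = FALSE)
data.table::fwrite(data.frame(id = names(sim$consensus_lengths),
                              length = unname(sim$consensus_lengths)),
                   file.path(out, "consensus_lengths.tsv"),
                   sep = "\t", col.names = FALSE)

conditions <- c("wing", "spermatocyte", "testis")
for (i in seq_along(conditions)) {
  lib <- simulate_fragment_library(sim, conditions[i], cfg,
                                   seed = seed + i, mark_mode = "body")
  write_bed(lib$fragments,
            file.path(out, paste0("fragments_", conditions[i], ".bed")))
  message(conditions[i], ": ", lib$library_size, " fragments")
}
# genotype trio: promoter-proximal mark, same underlying testis condition
trio <- c("bam", "aly", "wildtype")
for (i in seq_along(trio)) {
  lib <- simulate_fragment_library(sim, "testis", cfg, seed = seed + 10L + i,
                                   mark_mode = "promoter")
  write_bed(lib$fragments,
            file.path(out, paste0("fragments_", trio[i], ".bed")))
  message(trio[i], ": ", lib$library_size, " fragments")
}

atl <- simulate_expression_atlas(cfg, seed = seed + 20L,
                                 gene_ids = sim$genes$gene_id)
write_expression_atlas(atl$atlas, file.path(out, "atlas_matrix.tsv"),
                       file.path(out, "atlas_clusters.tsv"))
jsonlite::write_json(
  list(seed = seed,
       genes = sim$genes,
       archetypes = atl$truth,
       conditions = lapply(cfg$conditions, function(x) as.list(x$factors))),
  file.path(out, "truth.json"), digits = NA, auto_unbox = TRUE)
message("planted truth written; world ready under ", out)
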