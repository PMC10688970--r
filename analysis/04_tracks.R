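#!/usr/bin/env Rscript
# Step 4: export 20-kb binned CPM coverage tracks (bedGraph) for every
# library, for genome-browser or CIRCOS-style display.

suppressMessages(library(germchrom))

data_dir <- "results/data"
out <- "results/tracks"
chrom_sizes <- read_chrom_sizes(file.path(data_dir, "chrom.sizes"))
labels <- c("wing", "spermatocyte", "testis", "bam", "aly", "wildtype")
libs <- lapply(labels, function(lab) {
  load_fragments(file.path(data_dir, paste0("fragments_", lab, ".bed")),
                 lab, chrom_sizes)
})
run_track_export(libs, chrom_sizes, run_config(), out)
message(length(labels), " bedGraph tracks written to ", out)
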