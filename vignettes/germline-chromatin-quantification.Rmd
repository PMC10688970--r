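---
title: "Quantifying chromatin profiling signal in the fly male germline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chromatin profiling signal in the fly male germline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germchrom)
```

## The problem

Chromatin profiling of *Drosophila* testes (CUT&Tag-style assays on whole
tissue, stage-arrest mutants and FACS-isolated spermatocytes) produces
mapped fragment libraries whose interpretation requires a fixed chain of
quantification steps: a strand-aware promoter table from gene models,
fragment counting over promoter windows, gene bodies, transposon consensi
and fixed genomic bins, library-size scaling, cross-genotype z-scores to
time promoter activation, cell-type staging of genes from a single-nucleus
expression atlas, and chromosome-scale statistics that ask whether the
single male X is transcribed at one-copy or two-copy output.

`germchrom` implements that chain as a tested package, with a synthetic
generator that plants every quantity the chain is supposed to recover.

## Promoter model

For each transcript the TSS is its minimum coordinate on the `+` strand
and its maximum on the `-` strand. Duplicate TSSs within one gene collapse
to one record (the lexicographically smallest `transcript_id` is kept, so
output is deterministic); the same coordinate used by two distinct genes
yields one record per gene. The scoring window runs from 200 bp upstream
to 500 bp downstream of the TSS. We read "-200 to +500" as offsets
inclusive of the TSS, i.e. 701 bp unclipped; the single-basepair choice is
immaterial downstream but fixed here. Windows are strand-oriented
(mirrored for `-` promoters) by default because promoter architecture is
strand-asymmetric; `oriented = FALSE` lays the window left-to-right for
comparison, since the orientation convention is a genuine free choice.

Coordinates are converted exactly once: GTF input is 1-based inclusive,
everything internal and everything written to BED/bedGraph is 0-based
half-open, and the exported promoter table prints the TSS 1-based for
human readers.

For display filtering, each promoter is annotated with the nearest
promoter of a *different* gene lying 5' of it in its own orientation
(the neighbor's strand is ignored), with a flag for neighbors within
1 kb; ties at equal distance break to the smaller `gene_id`. Promoters of
the same gene never qualify as neighbors.

## Counting and scaling

A fragment counts once for every interval it overlaps by at least 1 bp
under the half-open test; a fragment spanning two intervals contributes
to both, and abutting intervals (`end == start`) do not overlap. Raw
counts are scaled as

- CPM = counts × 10^6 / library size,
- CPKM = CPM / (interval length in kb),

with the library size defined as the total retained fragment count.
Per-promoter activation timing uses z-scores over a genotype triple
(spermatogonium-arrested *bam*, early-spermatocyte-arrested *aly*, and
wildtype testes): `z = (x - mean) / sd` over the three CPM values with
the *population* SD (n = 3). With three samples the denominator choice
only rescales z by a constant and cannot reorder anything; zero-variance
promoters get all-zero z.

Binned tracks tile every chromosome from 0 in consecutive 20-kb bins
(last bin short) and are scaled as CPM per bin rather than by an
effective-genome-size constant: library-size scaling suffices for
within-genome comparison, and in the log2 ratio between two conditions
any common per-genome constant cancels. The log2 ratio adds a
pseudocount (default 1 CPM-bin unit) to both tracks so empty bins stay
finite.

Duplicate fragments are counted as given; deduplication and mate-pair
resolution are upstream mapping concerns. One fragment (not two mates)
is the counting unit.

## Expression staging

The atlas is a clusters × genes matrix of mean normalized expression
over 40 testis cell-type clusters: 18 germline clusters in developmental
order, 21 somatic clusters, and one unannotated cluster that enters no
summary. `cluster_means()` is a plain arithmetic mean of the supplied
normalized values per cluster; the normalization of the input matrix is
deliberately the caller's responsibility, since back-transformation
conventions differ between single-cell frameworks.

Per gene, `gexp` and `sexp` are means over the germline and somatic
clusters, and enrichment is `log2((gexp + eps)/(sexp + eps)) >= 1`
(inclusive). The pseudocount `eps = 0.01` keeps the ratio finite when
`sexp = 0` while leaving the decision unchanged for well-expressed
genes. Genes absent from the atlas are reported as missing, never
silently dropped.

Staging clusters per-gene profiles over all annotated clusters with
k-means (k = 10, k-means++-style restarts: 50 restarts under a fixed
seed). Profiles are z-scored per gene first; without row scaling,
absolute expression level dominates Euclidean distance and stage
structure is unrecoverable. Each k-cluster is called
germline-associated or somatic-associated by comparing its centroid's
mean (z-scale) mass over germline vs somatic clusters; all
somatic-associated clusters collapse into group "11", and
germline-associated clusters are numbered by the position of their
centroid peak along the germline order — clusters peaking at the same
position share a stage label, because with k larger than the number of
real expression programs k-means splits programs by noise, not shape.
The feature space (all annotated clusters vs germline only) is a
config switch; all annotated clusters is the default because staging is
defined relative to cell-type expression within the whole testis.

Published counts for the five germline stage groups are
initialization-dependent (the upstream seed is unreported), so they are
treated as approximate reference points, not contracts.

## Dosage statistics

Males carry one X and one Y but two copies of each autosome — including
the small fourth chromosome, which is diploid despite its X-like
evolutionary history. Gene-body CPKM scores are therefore doubled for X-
and Y-linked genes to express polymerase (or mark) density per gene
copy, then all scores are divided by the median per-copy score of genes
on the major autosome arms (2L/2R/3L/3R), pinning the autosomal median
at exactly 1. On this scale a dosage-compensated X has median ≈ 2 and an
uncompensated X has median ≈ 1. Because both doubling and CPKM are
linear, doubling raw counts or doubling CPKM is equivalent (asserted in
the test suite). Genes with a zero score in any profiled condition are
discarded before the statistics (filter, then double, then scale —
mirroring the display pipeline); quartiles use linear interpolation
(type 7), a display-level choice.

No significance test is attached: the claim is about medians, and the
package reports medians.

## The synthetic world

The generator emulates the statistical structure the analysis assumes,
at desk scale:

- **Genome**: 7 scaffolds (four 2-Mb autosome arms, 0.5-Mb fourth, 2-Mb
  X, 0.5-Mb Y) with 125 genes per arm, 10 fourth-chromosome genes
  (echoing how few genes that chromosome expresses), 100 X and 12 Y
  genes, placed without overlap (one slot per gene, random offset and
  strand), lengths uniform in 1–5 kb. Transposon consensi are extra
  scaffolds (16 by default, 1–8 kb).
- **Fragments**: per gene, Poisson counts with rate =
  depth × copies × per-gene rate × per-chromosome condition factor. The
  per-gene rate is lognormal around a base of 60 expected fragments per
  copy (mean-preserving, sdlog 0.25), comfortably above the ≥ 50
  fragments the recovery tests assume. Fragment midpoints are uniform
  over the gene body ("body" mode, elongating-polymerase-like), uniform
  over the −200..+500 promoter window ("promoter" mode,
  H3K4me2-like), or a 70/30 body/5'-biased mixture ("peaked"); lengths
  are truncated-normal(200, 50) in [50, 700], the paired-end insert
  window. A 5% uniform background is added, weighted per chromosome by
  length × condition factor — chromosome-wide silencing or activation
  (the heterochromatic Y) affects background as well as genes.
- **Conditions**: the somatic "wing" condition has X factor 2
  (compensated) and Y factor 0.05 (silenced); "spermatocyte" has X
  factor 1 (uncompensated) and Y factor 20 (activated); "testis" sits
  between. These plant the sign and magnitude of every chromosome-scale
  statistic the pipeline reports.
- **Atlas**: 40 clusters as above. Germline genes follow one of five
  Gaussian bumps (centers 2, 6, 10, 14, 17 along the 18-cluster order,
  width 2) times a lognormal amplitude (median 10), with a 2% baseline
  in somatic clusters; somatic genes are mirrored. Additive Gaussian
  noise (SD 0.1 on the unit bump scale) is clamped at zero; archetype
  separation is far above 5× this noise SD, which is what makes the
  ARI ≥ 0.9 staging recovery a fair target.

Everything downstream of a fixed seed is bit-reproducible.

What the generator does *not* emulate: mappability and repeat masking,
duplicate fragments, GC or accessibility bias, correlated noise between
neighboring genes, doublets or ambient RNA in the atlas, and real
cluster-annotation error. A green recovery test therefore establishes
that the estimators are correct and well-calibrated under the stated
model — not that the model captures every artifact of real libraries.

One acceptance-scale choice is worth recording: for the
500-genes-per-class dosage recovery run, the X scaffold is widened to
4 Mb so X gene lengths draw from the same 1–5 kb distribution as
autosomal genes. With a 2-Mb X, slot placement would truncate X genes
at 4 kb, and since CPKM scales with 1/length the class comparison would
inherit a ~20% bias that is a fixture artifact, not a property of the
pipeline.

The real-release bookkeeping constants (21,982 promoters, 144
cross-gene shared TSSs, 1,062 atlas-missing genes, 6,419
germline-enriched genes, a 40 × 15,833 atlas) require the FlyBase r6.31
GTF and the testis atlas deposit, which are not shipped; the census
machinery (`bookkeeping_report()`) is exercised exactly on synthetic
inputs, and asserts those constants whenever the optional files are
placed under `inst/extdata/real/`.

## Worked example

```{r example, eval = FALSE}
cfg <- synthetic_config()
sim <- simulate_annotation(cfg, seed = 1)
gtf <- tempfile(fileext = ".gtf"); writeLines(sim$gtf, gtf)
tx <- parse_gene_models(gtf)

wing  <- simulate_fragment_library(sim, "wing", cfg, seed = 2)
sperm <- simulate_fragment_library(sim, "spermatocyte", cfg, seed = 3)
res <- run_dosage_analysis(tx, list(wing, sperm), sim$chrom_sizes,
                           run_config(condition_pair = c("spermatocyte",
                                                         "wing")))
res$summaries$wing          # median scaled X ~ 2 (compensated)
res$summaries$spermatocyte  # median scaled X ~ 1 (uncompensated)
```

The numbered scripts under `analysis/` run the same chain from files on
disk (GTF, BED, chrom.sizes, atlas TSVs) and write all tables and
bedGraph tracks under `results/`.

## Known limitations

- BAM input is out of scope; the package consumes fragment BED intervals
  produced by an upstream mapper.
- Gene spans are union spans over isoforms; no isoform-resolved
  gene-body scoring.
- The nearest-upstream search is exact but quadratic per chromosome in
  the worst case; at genome scale (~22k promoters) this is still fast,
  but it is not built for millions of features.
- Stage labels beyond "follows the developmental order of centroid
  peaks" carry no absolute meaning; mapping them to named cell types is
  up to the caller's annotation.
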