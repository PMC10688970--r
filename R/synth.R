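## Synthetic-data generator. Emulates, at desk scale, the statistical
## structure the analysis assumes: a scaled-down fly genome (major
## autosome arms, fourth, X, Y, plus transposon consensus scaffolds),
## non-overlapping gene models, fragment libraries with per-gene Poisson
## counts whose rates combine copy number, a per-gene rate and a
## per-chromosome condition factor, and a staged 40-cluster expression
## atlas with five germline archetype profiles.

#' Default synthetic configuration
#'
#' The stated world of the simulations: a male genome (1 copy of X and Y,
#' 2 of everything else) of 7 scaled-down scaffolds, 500 major-autosome
#' genes (125 per arm), 100 X genes, 12 Y genes and 10 fourth-chromosome
#' genes; a base per-copy rate of 60 expected fragments per gene copy;
#' 5% uniform background; fragment lengths ~ truncated normal(200, 50)
#' in [50, 700] (the paired-end insert-size window); a 40-cluster atlas
#' (18 ordered germline, 21 somatic, 1 unannotated) with five germline
#' bump archetypes. Condition factors plant the dosage scenarios: the
#' somatic "wing" condition has a compensated X (per-copy rate x2) and a
#' near-silent heterochromatic Y; the "spermatocyte" condition has an
#' uncompensated X (x1) and a strongly activated Y.
#'
#' @param ... overrides for any default field.
#' @return a SyntheticConfig list.
#' @export
synthetic_config <- function(...) {
  cfg <- list(
    chrom_lengths = c("2L" = 2e6, "2R" = 2e6, "3L" = 2e6, "3R" = 2e6,
                      "4" = 5e5, "X" = 2e6, "Y" = 5e5),
    gene_counts = c("2L" = 125, "2R" = 125, "3L" = 125, "3R" = 125,
                    "4" = 10, "X" = 100, "Y" = 12),
    copies = c("2L" = 2, "2R" = 2, "3L" = 2, "3R" = 2,
               "4" = 2, "X" = 1, "Y" = 1),
    gene_length_range = c(1000L, 5000L),
    base_rate = 60,          # expected fragments per gene copy, factor 1
    rate_sdlog = 0.25,       # per-gene lognormal rate spread
    background_fraction = 0.05,
    fragment_length = list(mean = 200, sd = 50, min = 50, max = 700),
    conditions = list(
      wing = list(factors = c("X" = 2, "Y" = 0.05)),
      spermatocyte = list(factors = c("X" = 1, "Y" = 20)),
      testis = list(factors = c("X" = 1.5, "Y" = 5))
    ),
    n_consensus = 16L,
    consensus_length_range = c(1000L, 8000L),
    consensus_rate = 40,
    n_germline_clusters = 18L,
    n_somatic_clusters = 21L,
    archetype_centers = c(2, 6, 10, 14, 17),
    archetype_width = 2,
    amplitude_meanlog = log(10),
    amplitude_sdlog = 0.3,
    somatic_baseline = 0.02,  # fraction of amplitude leaking into the other role
    noise_sd = 0.1,           # additive, on the unit bump scale
    n_atlas_genes = 600L,
    germline_fraction = 5 / 6
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}

condition_factor <- function(config, condition, chrom) {
  f <- config$conditions[[condition]]$factors
  out <- rep(1, length(chrom))
  hit <- chrom %in% names(f)
  out[hit] <- unname(f[chrom[hit]])
  out
}

#' Simulate a gene annotation and chromosome table
#'
#' Places the configured number of non-overlapping genes per chromosome
#' (one slot per gene, random placement within the slot, random strand)
#' and emits GTF text that round-trips through [parse_gene_models()].
#' Transposon consensus scaffolds are appended to the chromosome table.
#'
#' @param config a [synthetic_config()].
#' @param seed RNG seed.
#' @return list with `gtf` (character vector of GTF lines), `chrom_sizes`
#'   (named integer vector, consensi included), `genes` (truth
#'   data.frame: gene_id, chrom, start, end 0-based half-open, strand,
#'   copies, rate), and `consensus_lengths`.
#' @export
simulate_annotation <- function(config = synthetic_config(), seed = 1L) {
  set.seed(seed)
  genes <- list()
  for (ch in names(config$gene_counts)) {
    n <- config$gene_counts[[ch]]
    L <- config$chrom_lengths[[ch]]
    slot <- floor(L / n)
    lmin <- config$gene_length_range[1L]
    lmax <- min(config$gene_length_range[2L], slot - 1L)
    if (lmax < lmin) {
      stop("chromosome ", ch, " too small for ", n, " genes of >= ",
           lmin, " bp")
    }
    len <- sample(lmin:lmax, n, replace = TRUE)
    offset <- vapply(slot - len, function(m) sample.int(m, 1L) - 1L, 0L)
    start <- (seq_len(n) - 1L) * slot + offset
    genes[[ch]] <- data.frame(
      gene_id = sprintf("SYN%s_%03d", ch, seq_len(n)),
      chrom = ch,
      start = as.integer(start),
      end = as.integer(start + len),
      strand = sample(c("+", "-"), n, replace = TRUE),
      copies = config$copies[[ch]],
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, c(genes, list(make.row.names = FALSE)))
  genes$rate <- config$base_rate *
    stats::rlnorm(nrow(genes), meanlog = -config$rate_sdlog^2 / 2,
                  sdlog = config$rate_sdlog)

  tx_id <- paste0(genes$gene_id, ".t1")
  attrs <- sprintf('gene_id "%s"; gene_symbol "%s"; transcript_id "%s";',
                   genes$gene_id, genes$gene_id, tx_id)
  gtf <- c(
    sprintf("%s\tsynthetic\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
            genes$chrom, genes$start + 1L, genes$end, genes$strand, attrs),
    sprintf("%s\tsynthetic\texon\t%d\t%d\t.\t%s\t.\t%s",
            genes$chrom, genes$start + 1L, genes$end, genes$strand, attrs))

  consensus_lengths <- integer(0)
  if (config$n_consensus > 0L) {
    consensus_lengths <- stats::setNames(
      sample(config$consensus_length_range[1L]:config$consensus_length_range[2L],
             config$n_consensus, replace = TRUE),
      sprintf("SYNTE%03d_consensus", seq_len(config$n_consensus)))
  }
  chrom_sizes <- c(stats::setNames(as.integer(config$chrom_lengths),
                                   names(config$chrom_lengths)),
                   consensus_lengths)
  list(gtf = gtf, chrom_sizes = chrom_sizes, genes = genes,
       consensus_lengths = consensus_lengths)
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

#' Simulate a fragment library for one condition
#'
#' Per gene, the realized fragment count is Poisson with rate
#' depth x copies x per-gene rate x chromosome condition factor.
#' Fragment midpoints fall uniformly over the gene body ("body" mode,
#' elongating-polymerase-like), over the promoter window ("promoter"
#' mode, active-promoter-mark-like), or over a 70/30 body/5'-peak
#' mixture ("peaked"). Lengths are truncated-normal; a uniform genomic
#' background and Poisson transposon-consensus fragments are added.
#'
#' @param sim output of [simulate_annotation()].
#' @param condition condition name present in the config.
#' @param config the [synthetic_config()] used for `sim`.
#' @param seed RNG seed.
#' @param depth depth multiplier on every rate (default 1; 0 gives an
#'   empty library).
#' @param mark_mode "body", "promoter" or "peaked".
#' @param te_factors optional named per-consensus rate multipliers.
#' @return a FragmentLibrary labeled `condition`.
#' @export
simulate_fragment_library <- function(sim, condition,
                                      config = synthetic_config(),
                                      seed = 1L, depth = 1,
                                      mark_mode = c("body", "promoter", "peaked"),
                                      te_factors = NULL) {
  mark_mode <- match.arg(mark_mode)
  set.seed(seed)
  genes <- sim$genes
  fl <- config$fragment_length
  if (depth <= 0) {
    return(fragment_library(data.frame(chrom = character(), start = integer(),
                                       end = integer()), condition, 0))
  }
  lambda <- depth * genes$copies * genes$rate *
    condition_factor(config, condition, genes$chrom)
  counts <- stats::rpois(nrow(genes), lambda)

  g_idx <- rep.int(seq_len(nrow(genes)), counts)
  n_sig <- length(g_idx)
  mid <- numeric(n_sig)
  if (n_sig > 0L) {
    gs <- genes$start[g_idx]; ge <- genes$end[g_idx]
    if (mark_mode == "body") {
      mid <- gs + stats::runif(n_sig) * (ge - gs)
    } else if (mark_mode == "promoter") {
      tss <- ifelse(genes$strand[g_idx] == "+", gs, ge - 1L)
      dir <- ifelse(genes$strand[g_idx] == "+", 1, -1)
      mid <- tss + dir * stats::runif(n_sig, -200, 500)
    } else {
      five <- gs + stats::runif(n_sig) * pmin(500, ge - gs)
      body <- gs + stats::runif(n_sig) * (ge - gs)
      mid <- ifelse(stats::runif(n_sig) < 0.3, five, body)
    }
  }
  frag_len <- if (n_sig > 0L) {
    round(rtruncnorm1(n_sig, fl$mean, fl$sd, fl$min, fl$max))
  } else integer(0)
  chrom <- genes$chrom[g_idx]

  # genomic background, uniform within a chromosome; the per-chromosome
  # condition factor scales background too (silencing or activation of a
  # heterochromatic chromosome is chromosome-wide, not gene-restricted)
  main <- names(config$chrom_lengths)
  n_bg <- stats::rpois(1L, config$background_fraction /
                         (1 - config$background_fraction) * sum(lambda))
  if (n_bg > 0L) {
    bg_ch <- sample(main, n_bg, replace = TRUE,
                    prob = config$chrom_lengths[main] *
                      condition_factor(config, condition, main))
    bg_mid <- stats::runif(n_bg) * config$chrom_lengths[bg_ch]
    chrom <- c(chrom, bg_ch)
    mid <- c(mid, bg_mid)
    frag_len <- c(frag_len,
                  round(rtruncnorm1(n_bg, fl$mean, fl$sd, fl$min, fl$max)))
  }

  # transposon consensus fragments
  if (length(sim$consensus_lengths) > 0L) {
    te_f <- rep(1, length(sim$consensus_lengths))
    names(te_f) <- names(sim$consensus_lengths)
    if (!is.null(te_factors)) te_f[names(te_factors)] <- te_factors
    te_counts <- stats::rpois(length(te_f), depth * config$consensus_rate * te_f)
    te_idx <- rep.int(seq_along(te_f), te_counts)
    if (length(te_idx) > 0L) {
      te_ch <- names(sim$consensus_lengths)[te_idx]
      te_mid <- stats::runif(length(te_idx)) * sim$consensus_lengths[te_idx]
      chrom <- c(chrom, te_ch)
      mid <- c(mid, te_mid)
      frag_len <- c(frag_len,
                    round(rtruncnorm1(length(te_idx), fl$mean, fl$sd,
                                      fl$min, fl$max)))
    }
  }

  sizes <- sim$chrom_sizes[chrom]
  start <- pmax(0, round(mid - frag_len / 2))
  end <- pmin(unname(sizes), start + frag_len)
  start <- pmin(start, end - 1)
  ord <- order(chrom, start, end)
  fragment_library(
    data.frame(chrom = chrom[ord], start = as.integer(start[ord]),
               end = as.integer(end[ord]), stringsAsFactors = FALSE),
    condition)
}

bump_profile <- function(n_clusters, center, width) {
  exp(-((seq_len(n_clusters) - center)^2) / (2 * width^2))
}

#' Simulate a staged expression atlas
#'
#' Germline genes follow one of five bump archetypes over the ordered
#' germline clusters, scaled by a lognormal amplitude, with a low
#' baseline in somatic clusters; somatic genes are the mirror image.
#' Additive Gaussian noise (SD on the unit bump scale) is clamped at 0.
#' The unannotated cluster carries baseline-level values.
#'
#' @param config a [synthetic_config()].
#' @param seed RNG seed.
#' @param gene_ids gene ids to simulate (default `config$n_atlas_genes`
#'   synthetic ids).
#' @return list with `atlas` (an ExpressionAtlas) and `truth` (data.frame:
#'   gene_id, archetype in 1..5 or "somatic", amplitude).
#' @export
simulate_expression_atlas <- function(config = synthetic_config(), seed = 1L,
                                      gene_ids = NULL) {
  set.seed(seed)
  if (is.null(gene_ids)) {
    gene_ids <- sprintf("SYNG%04d", seq_len(config$n_atlas_genes))
  }
  n <- length(gene_ids)
  ng <- config$n_germline_clusters
  ns <- config$n_somatic_clusters
  stopifnot(ng >= length(config$archetype_centers))
  ann <- cluster_annotation(
    c(sprintf("germline_%02d", seq_len(ng)),
      sprintf("somatic_%02d", seq_len(ns)), "unannotated"),
    c(rep("germline", ng), rep("somatic", ns), "unannotated"))

  n_arch <- length(config$archetype_centers)
  is_germ <- stats::runif(n) < config$germline_fraction
  archetype <- ifelse(is_germ,
                      as.character(sample.int(n_arch, n, replace = TRUE)),
                      "somatic")
  amplitude <- stats::rlnorm(n, config$amplitude_meanlog,
                             config$amplitude_sdlog)

  mat <- matrix(0, nrow = ng + ns + 1L, ncol = n,
                dimnames = list(ann$cluster_id, gene_ids))
  base <- config$somatic_baseline
  for (i in seq_len(n)) {
    if (archetype[i] == "somatic") {
      prof_g <- rep(base, ng)
      prof_s <- rep(1, ns)
    } else {
      a <- as.integer(archetype[i])
      prof_g <- bump_profile(ng, config$archetype_centers[a],
                             config$archetype_width)
      prof_s <- rep(base, ns)
    }
    prof <- c(prof_g, prof_s, base)
    mat[, i] <- amplitude[i] *
      pmax(0, prof + stats::rnorm(ng + ns + 1L, 0, config$noise_sd))
  }
  list(atlas = expression_atlas(mat, ann),
       truth = data.frame(gene_id = gene_ids, archetype = archetype,
                          amplitude = amplitude, stringsAsFactors = FALSE))
}

#' Analytic expectation of the dosage statistic
#'
#' On synthetic data the scaled per-copy score of a chromosome is, in
#' expectation, its planted per-copy factor relative to the
#' major-autosome factor — the oracle for recovery tests.
#'
#' @param config a [synthetic_config()].
#' @param condition condition name.
#' @param chrom chromosome name.
#' @return expected median scaled per-copy score.
#' @export
expected_scaled_score <- function(config, condition, chrom) {
  f <- condition_factor(config, condition, chrom)
  f_auto <- stats::median(condition_factor(config, condition,
                                           c("2L", "2R", "3L", "3R")))
  f / f_auto
}
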