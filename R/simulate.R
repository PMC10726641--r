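#' Configuration for the synthetic cohort simulator
#'
#' Defines the study conditions for a simulated full-length scRNA-seq cohort:
#' clonal somatic SNVs present in a tunable fraction of cells subject to
#' allelic dropout, germline SNVs present in most cells, RNA-editing sites at
#' moderate prevalence, and per-cell singleton artefacts with low-quality
#' evidence. Class-conditional quality distributions are separated so that
#' somatic and artefact calls are statistically distinguishable, as they are
#' in real data.
#'
#' @param n_cells Number of cells (>= 4; default 50).
#' @param n_somatic Number of clonal somatic SNVs (default 200).
#' @param somatic_prevalence Per-clone cell fraction carrying each somatic
#'   variant; a vector assigns variants to clones round-robin (default 0.4).
#' @param n_germline,germline_prevalence Germline SNV count and per-cell
#'   detection probability (defaults 100 and 0.95).
#' @param n_editing,editing_prevalence RNA-editing site count and prevalence
#'   (defaults 50 and 0.3).
#' @param artefact_rate Mean artefacts per cell (Poisson; default 20).
#' @param dropout Probability an expressed somatic variant is missed in a
#'   carrier cell (default 0.2).
#' @param depth_mu,depth_size Negative-binomial read-depth model for true
#'   variants (defaults 20 and 4).
#' @param artefact_depth_mu,artefact_depth_size Depth model for artefacts
#'   (defaults 6 and 2).
#' @param vaf_somatic,vaf_germline,vaf_artefact Beta(shape1, shape2)
#'   parameters of per-variant allele fractions.
#' @param qual_true,qual_artefact Normal(mean, sd) QUAL models.
#' @param qd_true,qd_artefact Normal QD models (artefacts sit mostly below
#'   the QD >= 2 filter).
#' @param fs_true_mean Exponential mean of FS for true variants.
#' @param fs_artefact Normal FS model for artefacts (mostly near or above the
#'   FS <= 30 filter).
#' @param caller_s_sensitivity Probability a true variant present in a cell is
#'   also emitted by the secondary caller (default 0.9).
#' @param caller_s_variant_miss Probability a true variant is systematically
#'   missed by the secondary caller in every cell (default 0.12).
#' @param artefact_in_s Probability an artefact call also appears in the
#'   secondary caller (default 0.05).
#' @param spectrum_bias Somatic SBS96 sampling weights: `"ct_biased"`
#'   (default; 60% of mass on C>T classes, cancer-like), `"uniform"`, or a
#'   numeric 96-vector.
#' @param ref_length,exon_fraction,exon_size Toy genome length (>= 10 kb),
#'   exonic fraction and exon tile size.
#' @param n_stages Number of stage labels cycled across cells (default 2).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cells = 50L, n_somatic = 200L,
                       somatic_prevalence = 0.4,
                       n_germline = 100L, germline_prevalence = 0.95,
                       n_editing = 50L, editing_prevalence = 0.3,
                       artefact_rate = 20, dropout = 0.2,
                       depth_mu = 20, depth_size = 4,
                       artefact_depth_mu = 6, artefact_depth_size = 2,
                       vaf_somatic = c(6, 4), vaf_germline = c(20, 20),
                       vaf_artefact = c(1.5, 8),
                       qual_true = c(150, 40), qual_artefact = c(35, 15),
                       qd_true = c(15, 5), qd_artefact = c(1.8, 1.2),
                       fs_true_mean = 3, fs_artefact = c(25, 15),
                       caller_s_sensitivity = 0.9,
                       caller_s_variant_miss = 0.12,
                       artefact_in_s = 0.05,
                       spectrum_bias = "ct_biased",
                       ref_length = 60000L, exon_fraction = 0.5,
                       exon_size = 300L, n_stages = 2L, seed = 17L) {
  if (n_cells < 4) abort("n_cells must be at least 4")
  if (ref_length < 10000) abort("ref_length must be at least 10 kb")
  probs <- c(somatic_prevalence, germline_prevalence, editing_prevalence,
             dropout, caller_s_sensitivity, caller_s_variant_miss, artefact_in_s)
  if (any(probs < 0 | probs > 1)) abort("all probabilities must lie in [0, 1]")
  if (any(somatic_prevalence >= germline_prevalence)) {
    abort("somatic prevalence must be below germline prevalence")
  }
  exp_rec <- min(somatic_prevalence) * n_cells * (1 - dropout)
  if (exp_rec < 3) {
    warn(sprintf(paste("expected somatic recurrence %.1f is below the default",
                       "recurrence floor of 3; the core filter may find nothing"),
                 exp_rec))
  }
  cfg <- as.list(environment())
  cfg$probs <- NULL
  cfg$exp_rec <- NULL
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

somatic_spectrum <- function(spectrum_bias) {
  if (is.numeric(spectrum_bias)) {
    stopifnot(length(spectrum_bias) == 96, all(spectrum_bias >= 0))
    return(spectrum_bias / sum(spectrum_bias))
  }
  cat96 <- sbs96_catalog()
  if (identical(spectrum_bias, "uniform")) return(rep(1 / 96, 96))
  if (identical(spectrum_bias, "ct_biased")) {
    w <- rep(0.4 / 80, 96)
    w[cat96$mutation_type == "C>T"] <- 0.6 / 16
    return(w)
  }
  abort("spectrum_bias must be 'ct_biased', 'uniform', or a 96-vector")
}

#' Generate a toy reference genome with exon and gene annotations
#'
#' A single random-sequence contig tiled with fixed-size exons covering
#' approximately `exon_fraction` of the genome; every five consecutive exons
#' form a named gene span. Deterministic given the seed.
#'
#' @param length Contig length in bases (>= 10 kb).
#' @param exon_fraction Fraction of the genome covered by exons.
#' @param exon_size Exon tile size in bases.
#' @param seed Integer seed.
#' @return List with `genome` (a named `DNAStringSet`, contig `chr1`),
#'   `exons` and `genes` (both [GenomicRanges::GRanges]).
#' @export
generate_reference <- function(length = 60000L, exon_fraction = 0.5,
                               exon_size = 300L, seed = 17L) {
  if (length < 10000) abort("reference length must be at least 10 kb")
  set.seed(seed)
  seq <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
               collapse = "")
  genome <- Biostrings::DNAStringSet(seq)
  names(genome) <- "chr1"
  period <- round(exon_size / exon_fraction)
  starts <- seq(1L, length - exon_size, by = period)
  exons <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(starts, width = exon_size))
  n_genes <- ceiling(base::length(starts) / 5)
  gene_of <- rep(seq_len(n_genes), each = 5)[seq_along(starts)]
  gene_start <- tapply(starts, gene_of, min)
  gene_end <- tapply(starts + exon_size - 1L, gene_of, max)
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(as.integer(gene_start), as.integer(gene_end)),
    name = sprintf("gene%03d", seq_len(n_genes)))
  list(genome = genome, exons = exons, genes = genes)
}

rnorm_trunc <- function(n, mean, sd, lower) pmax(rnorm(n, mean, sd), lower)

# Sample variant keys whose SBS96 classes follow `weights`, from the pool of
# exonic positions. Falls back to a uniform position with random alt when the
# wanted context bucket is exhausted.
sample_spectrum_keys <- function(n, weights, pool) {
  cat96 <- sbs96_catalog()
  picked <- integer(0)
  alts <- character(0)
  cls <- sample(96, n, replace = TRUE, prob = weights)
  for (k in cls) {
    bucket <- which(pool$ctx_pyr == cat96$context[k] & !pool$used)
    if (base::length(bucket) == 0) bucket <- which(!pool$used)
    i <- bucket[sample.int(base::length(bucket), 1L)]
    pool$used[i] <- TRUE
    picked <- c(picked, i)
    want_alt <- substr(cat96$mutation_type[k], 3, 3)
    alt <- if (pool$ctx_pyr[i] == cat96$context[k]) {
      if (pool$flipped[i]) unname(COMPLEMENT[want_alt]) else want_alt
    } else {
      sample(setdiff(c("A", "C", "G", "T"), pool$ref[i]), 1L)
    }
    alts <- c(alts, alt)
  }
  list(keys = tibble(chrom = "chr1", pos = pool$pos[picked],
                     ref = pool$ref[picked], alt = alts),
       pool = pool)
}

#' Simulate a paired-caller single-cell variant cohort with known truth
#'
#' Generates a toy reference, plants somatic, germline and RNA-editing
#' variants plus per-cell artefacts, draws class-conditional depth, allele
#' counts and quality values, and writes per-cell VCF pairs (primary and
#' secondary caller), the cohort manifest, site lists, a truth VCF and a
#' ground-truth table — everything [resa_run()] consumes.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Object of class `resa_sim`: list with `dir`, `paths` (named file
#'   paths: `manifest`, `ref`, `exons`, `genes`, `editing`, `germline`,
#'   `truth_vcf`, `truth_tsv`, `stages`), `truth` (per-key class/clone
#'   tibble), `presence` (per key x cell presence of true variants) and
#'   `config`.
#' @export
simulate_cohort <- function(cfg = sim_config(), dir) {
  dir.create(file.path(dir, "cells"), recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  ref <- generate_reference(cfg$ref_length, cfg$exon_fraction, cfg$exon_size,
                            seed = cfg$seed)
  seq_chr <- as.character(ref$genome[[1]])
  len <- nchar(seq_chr)

  # pool of exonic positions with pyrimidine-collapsed trinucleotide context
  pos <- unlist(lapply(seq_along(ref$exons), function(i) {
    seq(GenomicRanges::start(ref$exons)[i], GenomicRanges::end(ref$exons)[i])
  }))
  pos <- pos[pos >= 2 & pos <= len - 1]
  ctx <- substring(seq_chr, pos - 1L, pos + 1L)
  center <- substr(ctx, 2, 2)
  flipped <- center %in% c("A", "G")
  pool <- list(pos = pos, ref = center, flipped = flipped,
               ctx_pyr = ifelse(flipped, revcomp_chr(ctx), ctx),
               used = rep(FALSE, base::length(pos)))

  som <- sample_spectrum_keys(cfg$n_somatic, somatic_spectrum(cfg$spectrum_bias),
                              pool)
  pool <- som$pool
  draw_uniform_keys <- function(n, pool) {
    avail <- which(!pool$used)
    i <- sample(avail, n)
    pool$used[i] <- TRUE
    alt <- vapply(pool$ref[i],
                  function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                  character(1))
    list(keys = tibble(chrom = "chr1", pos = pool$pos[i], ref = pool$ref[i],
                       alt = unname(alt)), pool = pool)
  }
  germ <- draw_uniform_keys(cfg$n_germline, pool); pool <- germ$pool
  edit <- draw_uniform_keys(cfg$n_editing, pool); pool <- edit$pool

  clones <- rep(seq_along(cfg$somatic_prevalence), length.out = cfg$n_somatic)
  truth <- bind_rows(
    mutate(som$keys, class = "somatic", clone = clones,
           prevalence = cfg$somatic_prevalence[clones]),
    mutate(germ$keys, class = "germline", clone = NA_integer_,
           prevalence = cfg$germline_prevalence),
    mutate(edit$keys, class = "editing", clone = NA_integer_,
           prevalence = cfg$editing_prevalence)
  )
  truth$vaf <- c(rbeta(cfg$n_somatic, cfg$vaf_somatic[1], cfg$vaf_somatic[2]),
                 rbeta(cfg$n_germline, cfg$vaf_germline[1], cfg$vaf_germline[2]),
                 rbeta(cfg$n_editing, cfg$vaf_somatic[1], cfg$vaf_somatic[2]))
  truth$s_miss <- runif(nrow(truth)) < cfg$caller_s_variant_miss

  cell_ids <- sprintf("cell%03d", seq_len(cfg$n_cells))
  present_prob <- ifelse(truth$class == "somatic",
                         truth$prevalence * (1 - cfg$dropout), truth$prevalence)
  presence <- matrix(runif(nrow(truth) * cfg$n_cells) <
                       rep(present_prob, cfg$n_cells),
                     nrow = nrow(truth))
  colnames(presence) <- cell_ids

  contig_len <- c(chr1 = len)
  avail_artefact <- pool$pos[!pool$used]
  manifest <- tibble(cell_id = cell_ids,
                     vcf_g = file.path("cells", paste0(cell_ids, "_G.vcf")),
                     vcf_s = file.path("cells", paste0(cell_ids, "_S.vcf")),
                     stage = sprintf("stage%d",
                                     rep_len(seq_len(cfg$n_stages), cfg$n_cells)))

  for (ci in seq_len(cfg$n_cells)) {
    idx <- which(presence[, ci])
    dp <- rnbinom(base::length(idx), mu = cfg$depth_mu, size = cfg$depth_size)
    ad_alt <- rbinom(base::length(idx), dp, truth$vaf[idx])
    seen <- dp > 0 & ad_alt > 0
    idx <- idx[seen]; dp <- dp[seen]; ad_alt <- ad_alt[seen]
    n_t <- base::length(idx)
    true_calls <- tibble(
      chrom = "chr1", pos = truth$pos[idx], ref = truth$ref[idx],
      alt = truth$alt[idx], cell_id = cell_ids[ci], caller = "G",
      dp = dp, ad_ref = dp - ad_alt, ad_alt = ad_alt, vaf = ad_alt / dp,
      qual = round(rnorm_trunc(n_t, cfg$qual_true[1], cfg$qual_true[2], 20), 2),
      fs = round(rexp(n_t, 1 / cfg$fs_true_mean), 2),
      qd = round(rnorm_trunc(n_t, cfg$qd_true[1], cfg$qd_true[2], 0.1), 2),
      s_emit = !truth$s_miss[idx] & runif(n_t) < cfg$caller_s_sensitivity
    )

    n_a <- rpois(1, cfg$artefact_rate)
    apos <- sample(avail_artefact, min(n_a, base::length(avail_artefact)))
    aref <- substring(seq_chr, apos, apos)
    aalt <- vapply(aref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                   character(1))
    adp <- 1L + rnbinom(base::length(apos), mu = cfg$artefact_depth_mu,
                        size = cfg$artefact_depth_size)
    avaf <- rbeta(base::length(apos), cfg$vaf_artefact[1], cfg$vaf_artefact[2])
    aad <- pmin(adp, pmax(1L, rbinom(base::length(apos), adp, avaf)))
    art_calls <- tibble(
      chrom = "chr1", pos = apos, ref = aref, alt = unname(aalt),
      cell_id = cell_ids[ci], caller = "G",
      dp = adp, ad_ref = adp - aad, ad_alt = aad, vaf = aad / adp,
      qual = round(rnorm_trunc(base::length(apos), cfg$qual_artefact[1],
                               cfg$qual_artefact[2], 2), 2),
      fs = round(rnorm_trunc(base::length(apos), cfg$fs_artefact[1],
                             cfg$fs_artefact[2], 0), 2),
      qd = round(rnorm_trunc(base::length(apos), cfg$qd_artefact[1],
                             cfg$qd_artefact[2], 0.05), 2),
      s_emit = runif(base::length(apos)) < cfg$artefact_in_s
    )

    cell <- bind_rows(true_calls, art_calls) |>
      mutate(pl_1 = round(pmin(.data$qual, 250)), pl_2 = 0,
             pl_3 = round(3 * .data$ad_ref + 10),
             read_pos_bias = NA_real_, pass_flag = TRUE) |>
      arrange_keys()
    write_calls_vcf(select(cell, -"s_emit"),
                    file.path(dir, "cells", paste0(cell_ids[ci], "_G.vcf")),
                    caller = "G", contig_lengths = contig_len)
    s_cell <- filter(cell, .data$s_emit) |>
      mutate(qual = NA_real_, fs = NA_real_, qd = NA_real_,
             pl_1 = NA_real_, pl_2 = NA_real_, pl_3 = NA_real_)
    write_calls_vcf(select(s_cell, -"s_emit"),
                    file.path(dir, "cells", paste0(cell_ids[ci], "_S.vcf")),
                    caller = "S", contig_lengths = contig_len)
  }

  paths <- list(
    manifest = file.path(dir, "manifest.tsv"),
    ref = file.path(dir, "ref.fa"),
    exons = file.path(dir, "exons.bed"),
    genes = file.path(dir, "genes.bed"),
    editing = file.path(dir, "editing_sites.tsv"),
    germline = file.path(dir, "germline_sites.tsv"),
    truth_vcf = file.path(dir, "truth.vcf"),
    truth_tsv = file.path(dir, "sim_truth.tsv"),
    stages = file.path(dir, "stages.tsv")
  )
  readr::write_tsv(manifest, paths$manifest, progress = FALSE)
  Biostrings::writeXStringSet(ref$genome, paths$ref)
  rtracklayer::export(ref$exons, paths$exons, format = "BED")
  rtracklayer::export(ref$genes, paths$genes, format = "BED")
  readr::write_tsv(arrange(edit$keys[, c("chrom", "pos")], .data$pos),
                   paths$editing, progress = FALSE)
  readr::write_tsv(arrange(germ$keys, .data$pos), paths$germline,
                   progress = FALSE)
  write_sites_vcf(som$keys, paths$truth_vcf, contig_lengths = contig_len)
  readr::write_tsv(arrange_keys(truth[, c(KEY_COLS, "class", "clone",
                                          "prevalence", "vaf")]),
                   paths$truth_tsv, progress = FALSE)
  readr::write_tsv(manifest[, c("cell_id", "stage")], paths$stages,
                   progress = FALSE)

  structure(list(dir = dir, paths = paths, truth = truth,
                 presence = presence, config = cfg),
            class = "resa_sim")
}

#' Ready-made simulation presets
#'
#' `tiny` (12 cells / 20 somatic SNVs) is sized for fast checks; `default`
#' (50 cells / 200 somatic) matches the package's standard study conditions;
#' `high_burden` (50 cells / 2,000 somatic on a longer genome) exercises the
#' high-mutation-burden regime where classifier refinement pays off most.
#'
#' @param preset One of `"tiny"`, `"default"`, `"high_burden"`.
#' @param dir Output directory.
#' @param seed Integer seed (default 17).
#' @return A `resa_sim` object (see [simulate_cohort()]).
#' @export
simulate_preset <- function(preset = c("tiny", "default", "high_burden"),
                            dir, seed = 17L) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    tiny = sim_config(n_cells = 12L, n_somatic = 20L, n_germline = 30L,
                      n_editing = 10L, artefact_rate = 8, ref_length = 20000L,
                      seed = seed),
    default = sim_config(seed = seed),
    high_burden = sim_config(n_somatic = 2000L, ref_length = 200000L,
                             seed = seed)
  )
  simulate_cohort(cfg, dir)
}
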