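#' F0.5 score
#'
#' The precision-weighted F score,
#' \eqn{F_{0.5} = 1.25 \cdot \frac{precision \cdot sensitivity}
#' {0.25 \cdot precision + sensitivity}}, i.e. the general \eqn{F_\beta}
#' at \eqn{\beta = 0.5}. Undefined (`NA`) when both inputs are 0.
#'
#' @param precision,sensitivity Fractions in \[0, 1\] (vectorized).
#' @return Numeric vector of scores.
#' @export
#' @examples
#' f_half(0.8, 0.4)  # 0.6667
#' f_half(0.5, 0.5)  # identical inputs give that value back
f_half <- function(precision, sensitivity) {
  if (any(precision < 0 | precision > 1 | sensitivity < 0 | sensitivity > 1,
          na.rm = TRUE)) {
    abort("precision and sensitivity must lie in [0, 1]")
  }
  ifelse(precision == 0 & sensitivity == 0, NA_real_,
         1.25 * precision * sensitivity / (0.25 * precision + sensitivity))
}

#' Overlap coefficient of two sets
#'
#' \eqn{overlap(X, Y) = |X \cap Y| / \min(|X|, |Y|)} — the replicate
#' consistency measure. Accepts character vectors or key tibbles.
#'
#' @param x,y Sets, as character vectors or data frames with key columns.
#' @return The overlap coefficient; `NA` with a warning if a set is empty.
#' @export
overlap_coefficient <- function(x, y) {
  as_set <- function(s) unique(if (is.data.frame(s)) key_id(s) else as.character(s))
  x <- as_set(x); y <- as_set(y)
  if (length(x) == 0 || length(y) == 0) {
    warn("overlap coefficient undefined for an empty set")
    return(NA_real_)
  }
  length(intersect(x, y)) / min(length(x), length(y))
}

#' Evaluate a predicted variant set against a truth set
#'
#' Counts true positives, false positives and false negatives by exact
#' variant-key matching and reports precision, sensitivity and F0.5.
#' Ratios with a zero denominator are reported as `NA` (undefined), not 0.
#'
#' @param predicted Key tibble (or character key vector) of predicted somatic
#'   SNVs.
#' @param truth Key tibble (or character vector) of true somatic SNVs
#'   (WES-derived or simulator ground truth).
#' @return One-row tibble: `tp`, `fp`, `fn`, `precision`, `sensitivity`,
#'   `f_half`.
#' @export
evaluate_against_truth <- function(predicted, truth) {
  as_set <- function(s) unique(if (is.data.frame(s)) key_id(s) else as.character(s))
  p <- as_set(predicted); t <- as_set(truth)
  if (length(p) == 0) warn("empty predicted set: precision is undefined")
  tp <- length(intersect(p, t)); fp <- length(setdiff(p, t))
  fn <- length(setdiff(t, p))
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  sensitivity <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  fh <- if (!is.na(precision) && !is.na(sensitivity)) f_half(precision, sensitivity)
        else NA_real_
  tibble(tp = tp, fp = fp, fn = fn, precision = precision,
         sensitivity = sensitivity, f_half = fh)
}

#' SBS96 mutational spectrum of a variant set
#'
#' Counts each key's pyrimidine-centric SBS96 class; keys with undefined
#' context (N in the flank) are excluded and counted.
#'
#' @param keys Key tibble.
#' @param reference FASTA path or `DNAStringSet`.
#' @return Object of class `resa_spectrum`: the [sbs96_catalog()] tibble with
#'   a `count` column; attributes `total` and `n_undefined`.
#' @export
mutation_spectrum <- function(keys, reference) {
  keys <- distinct(as_tibble(keys)[, KEY_COLS])
  cat96 <- sbs96_catalog()
  if (nrow(keys) == 0) {
    warn("empty key set: all-zero spectrum")
    cls <- integer(0)
  } else {
    cls <- sbs96_context(keys, reference)$sbs96_class
  }
  counts <- tabulate(cls[!is.na(cls)] + 1L, nbins = 96)
  out <- mutate(cat96, count = counts)
  attr(out, "total") <- sum(counts)
  attr(out, "n_undefined") <- sum(is.na(cls))
  class(out) <- c("resa_spectrum", class(out))
  out
}

#' Cosine similarity of two SBS96 spectra
#'
#' @param a,b `resa_spectrum` objects or numeric 96-vectors of counts.
#' @return Cosine similarity in \[0, 1\]; `NA` for a zero vector.
#' @export
cosine_similarity <- function(a, b) {
  as_vec <- function(s) if (is.data.frame(s)) s$count else as.numeric(s)
  a <- as_vec(a); b <- as_vec(b)
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    warn("cosine similarity undefined for a zero spectrum")
    return(NA_real_)
  }
  sum(a * b) / (na * nb)
}

#' @describeIn mutation_spectrum Classic 96-channel spectrum bar chart.
#' @param object A `resa_spectrum`.
#' @param ... Unused.
#' @export
autoplot.resa_spectrum <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(label = factor(.data$label, levels = .data$label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$count,
                                   fill = .data$mutation_type)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(~mutation_type, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "SNVs", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 4),
                   legend.position = "none")
}

#' Stage-specific enrichment of mutated genes
#'
#' For each (gene, stage) pair, tests whether mutation-carrying cells are
#' over-represented in that stage with the upper tail of the hypergeometric
#' distribution: with N cells in total, K carriers of the gene's mutations,
#' and n cells in the stage of which k are carriers,
#' `p = P[X >= k], X ~ Hypergeometric(N, K, n)`. A gene is flagged enriched at
#' a stage when `p < alpha` (raw threshold, default 0.05); Benjamini-Hochberg
#' adjusted p-values are reported alongside for transparency.
#'
#' @param carriers Tibble with columns `gene`, `stage`, `k` (carrier cells of
#'   that gene in that stage).
#' @param stage_sizes Tibble with columns `stage`, `n` (cells per stage; the
#'   stages partition the cohort).
#' @param alpha Raw significance threshold (default 0.05).
#' @return Tibble: `gene`, `stage`, `k`, `n`, `K`, `N`, `p_value`,
#'   `p_adjust_bh`, `enriched`.
#' @export
stage_enrichment <- function(carriers, stage_sizes, alpha = 0.05) {
  carriers <- as_tibble(carriers)
  stage_sizes <- as_tibble(stage_sizes)
  N <- sum(stage_sizes$n)
  out <- carriers |>
    tidyr::complete(gene = unique(carriers$gene), stage = stage_sizes$stage,
                    fill = list(k = 0L)) |>
    left_join(stage_sizes, by = "stage") |>
    group_by(.data$gene) |>
    mutate(K = sum(.data$k)) |>
    ungroup() |>
    mutate(N = N)
  if (any(out$k > pmin(out$n, out$K))) {
    abort("inconsistent counts: k exceeds min(n, K) for some (gene, stage)")
  }
  out |>
    mutate(p_value = phyper(.data$k - 1, .data$K, .data$N - .data$K, .data$n,
                            lower.tail = FALSE),
           p_adjust_bh = p.adjust(.data$p_value, method = "BH"),
           enriched = .data$p_value < alpha) |>
    arrange(.data$gene, .data$stage)
}

#' Count mutation-carrying cells per gene and stage
#'
#' Assigns each variant key to the first overlapping gene (alphabetical on
#' ties), then counts, per gene and stage, the cells carrying at least one
#' mutant variant of that gene.
#'
#' @param calls Call tibble restricted to the variant set of interest (e.g.
#'   the supporting calls of the final positive keys).
#' @param genes [GenomicRanges::GRanges] of gene spans with a `name` column.
#' @param stages Tibble with `cell_id`, `stage`.
#' @return List with `carriers` (gene, stage, k) and `stage_sizes`
#'   (stage, n), ready for [stage_enrichment()].
#' @export
carrier_counts <- function(calls, genes, stages) {
  calls <- as_tibble(calls)
  q <- GenomicRanges::GRanges(calls$chrom, IRanges::IRanges(calls$pos, calls$pos))
  hits <- GenomicRanges::findOverlaps(q, genes)
  gene_names <- genes$name
  assigned <- tibble(row = S4Vectors::queryHits(hits),
                     gene = gene_names[S4Vectors::subjectHits(hits)]) |>
    group_by(.data$row) |>
    summarise(gene = min(.data$gene), .groups = "drop")
  carriers <- calls |>
    mutate(row = dplyr::row_number()) |>
    inner_join(assigned, by = "row") |>
    inner_join(stages, by = "cell_id") |>
    distinct(.data$gene, .data$stage, .data$cell_id) |>
    count(.data$gene, .data$stage, name = "k")
  stage_sizes <- count(stages, .data$stage, name = "n")
  list(carriers = carriers, stage_sizes = stage_sizes)
}
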