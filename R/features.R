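QUALITY_FEATURES <- c("qual", "dp", "vaf", "pl_1", "pl_2", "pl_3",
                      "ad_ref", "ad_alt")

#' Quality-based features for each call
#'
#' Extracts the quality evidence the classifier's quality submodel consumes:
#' variant quality, read depth, variant allele fraction, the min-normalized
#' Phred genotype likelihood triple, and the two allele depths. PL values are
#' re-normalized so their minimum is 0 (a no-op for already-normalized input).
#'
#' @param calls Call tibble with `dp > 0` and a 3-entry PL.
#' @return Tibble with the key/cell columns and the 8 quality feature columns.
#' @export
quality_features <- function(calls) {
  calls <- as_tibble(calls)
  if (any(is.na(calls$dp) | calls$dp <= 0)) {
    abort("quality features require dp > 0 for every call")
  }
  plmin <- pmin(calls$pl_1, calls$pl_2, calls$pl_3)
  calls |>
    mutate(pl_1 = .data$pl_1 - plmin, pl_2 = .data$pl_2 - plmin,
           pl_3 = .data$pl_3 - plmin) |>
    select(dplyr::all_of(c(KEY_COLS, "cell_id")), dplyr::all_of(QUALITY_FEATURES))
}

#' Sequence-based features for each variant key
#'
#' One-hot encodes the mutation type (6 classes) and SBS96 trinucleotide
#' context (96 classes) of each key, plus optional mutation-signature
#' components: for a supplied K x 96 reference signature matrix, component k
#' of a variant is signature k's probability mass on the variant's SBS96
#' class.
#'
#' @param keys Key tibble (`chrom`, `pos`, `ref`, `alt`).
#' @param reference FASTA path or `DNAStringSet`.
#' @param signatures Optional numeric matrix (rows = signatures, 96 columns in
#'   canonical SBS96 order) or path to such a TSV
#'   (see [read_signature_matrix()]).
#' @return Tibble: key columns, `sbs96_class`, then `mt_*` (6 columns),
#'   `ctx_*` (96 columns) and `sig_*` (K columns) features. Keys with
#'   undefined context get `NA` features and are excluded downstream.
#' @export
sequence_features <- function(keys, reference, signatures = NULL) {
  cat96 <- sbs96_catalog()
  keys <- sbs96_context(as_tibble(keys)[, KEY_COLS], reference)
  mt_levels <- unique(cat96$mutation_type)
  mt <- cat96$mutation_type[match(keys$sbs96_class, cat96$class)]
  mt_oh <- outer(mt, mt_levels, `==`) * 1
  colnames(mt_oh) <- paste0("mt_", sub(">", "to", mt_levels))
  ctx_oh <- outer(keys$sbs96_class, cat96$class, `==`) * 1
  colnames(ctx_oh) <- paste0("ctx_", cat96$label)
  out <- dplyr::bind_cols(keys[, c(KEY_COLS, "sbs96_class")],
                          as_tibble(mt_oh), as_tibble(ctx_oh))
  if (!is.null(signatures)) {
    if (is.character(signatures)) signatures <- read_signature_matrix(signatures)
    if (ncol(signatures) != 96) abort("signature matrix must have 96 columns")
    comp <- t(signatures)[keys$sbs96_class + 1L, , drop = FALSE]
    colnames(comp) <- paste0("sig_", rownames(signatures) %||% seq_len(nrow(signatures)))
    out <- dplyr::bind_cols(out, as_tibble(comp))
  }
  out
}

#' Read a reference mutational-signature matrix
#'
#' Expects a TSV whose first column names the signatures and whose remaining
#' 96 columns are headed by canonical SBS96 labels (e.g. `A[C>A]A`), in any
#' order; columns are rearranged into canonical order.
#'
#' @param path TSV path.
#' @return Numeric matrix, one row per signature, 96 columns.
#' @export
read_signature_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  labels <- sbs96_catalog()$label
  if (!all(labels %in% names(df))) {
    abort("signature TSV must have all 96 canonical SBS96 context columns")
  }
  m <- as.matrix(df[, labels])
  rownames(m) <- as.character(df[[1]])
  m
}

#' Build design matrices for the joint classifier
#'
#' Assembles one row per labeled variant key. Quality features are aggregated
#' across a key's supporting calls (arithmetic mean by default, or the call
#' with maximal QUAL); sequence features are per-key. Row order is
#' deterministic (sorted by key), and prediction matrices for the unsure set
#' share the training column layout exactly.
#'
#' @param labeling A `resa_labeling` from [label_cohort()] / [resa_label()].
#' @param reference FASTA path or `DNAStringSet`.
#' @param signatures Optional signature matrix or TSV path.
#' @param aggregate `"mean"` (default) or `"max_qual"`.
#' @return List with elements `labeled` and `unsure`, each a list of
#'   `quality` (matrix), `sequence` (matrix), `keys` (tibble) and, for
#'   `labeled`, `y` (0/1 vector; positive = 1). Keys whose sequence context is
#'   undefined are dropped from both matrices and listed in `dropped`.
#' @export
build_design_matrices <- function(labeling, reference, signatures = NULL,
                                  aggregate = c("mean", "max_qual")) {
  aggregate <- match.arg(aggregate)
  labels <- labeling$labels
  if (!any(labels$label == "positive") || !any(labels$label == "negative")) {
    abort(paste("both a positive and a negative class are required to fit the",
                "classifier; relax filtering thresholds"))
  }
  calls <- filter(labeling$calls, !is.na(.data$dp) & .data$dp > 0)
  qf <- quality_features(calls)
  agg <- if (aggregate == "mean") {
    qf |>
      group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
      summarise(across(dplyr::all_of(QUALITY_FEATURES), mean), .groups = "drop")
  } else {
    qf |>
      group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
      dplyr::slice_max(.data$qual, n = 1, with_ties = FALSE) |>
      ungroup() |>
      select(-"cell_id")
  }

  one_side <- function(keys) {
    keys <- arrange_keys(keys[, KEY_COLS])
    q <- inner_join(keys, agg, by = KEY_COLS)
    s <- sequence_features(q[, KEY_COLS], reference, signatures)
    ok <- !is.na(s$sbs96_class)
    dropped <- q[!ok, KEY_COLS]
    q <- q[ok, ]
    s <- s[ok, ]
    list(keys = q[, KEY_COLS],
         quality = as.matrix(q[, QUALITY_FEATURES]),
         sequence = as.matrix(s[, setdiff(names(s), c(KEY_COLS, "sbs96_class"))]),
         dropped = dropped)
  }

  lab_keys <- filter(labels, .data$label %in% c("positive", "negative"))
  labeled <- one_side(lab_keys)
  y_map <- setNames(as.integer(lab_keys$label == "positive"), key_id(lab_keys))
  labeled$y <- unname(y_map[key_id(labeled$keys)])
  unsure <- one_side(filter(labels, .data$label == "unsure"))
  stopifnot(identical(colnames(labeled$quality), colnames(unsure$quality)),
            identical(colnames(labeled$sequence), colnames(unsure$sequence)))
  list(labeled = labeled, unsure = unsure)
}
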