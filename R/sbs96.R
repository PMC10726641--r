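#' The canonical SBS96 catalog
#'
#' Single-base substitutions are classified into 96 strand-collapsed classes:
#' 6 pyrimidine-centric mutation types (C>A, C>G, C>T, T>A, T>C, T>G) crossed
#' with the 16 combinations of 5' and 3' flanking bases. Classes are ordered
#' lexicographically by (mutation type, 5' base, 3' base), so `A[C>A]A` is
#' class 0 and `T[T>G]T` is class 95.
#'
#' @return A 96-row tibble with columns `class` (integer 0..95), `label`
#'   (e.g. `"A[C>A]A"`), `mutation_type` (e.g. `"C>A"`), `five` and `three`
#'   (flanking bases), and `context` (the trinucleotide, e.g. `"ACA"`).
#' @export
#' @examples
#' sbs96_catalog()
sbs96_catalog <- function() {
  bases <- c("A", "C", "G", "T")
  types <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  grid <- expand.grid(three = bases, five = bases, mutation_type = types,
                      stringsAsFactors = FALSE)[, 3:1]
  tibble::as_tibble(grid) |>
    mutate(
      class = dplyr::row_number() - 1L,
      pyr = substr(.data$mutation_type, 1, 1),
      context = paste0(.data$five, .data$pyr, .data$three),
      label = paste0(.data$five, "[", .data$mutation_type, "]", .data$three)
    ) |>
    select("class", "label", "mutation_type", "five", "three", "context")
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp_chr <- function(x) {
  # reverse-complement of short base strings, vectorized
  vapply(strsplit(x, ""), function(b) paste(rev(unname(COMPLEMENT[b])), collapse = ""),
         character(1))
}

#' Resolve trinucleotide context and SBS96 class for variant keys
#'
#' Looks up the reference trinucleotide around each SNV and assigns the
#' pyrimidine-centric SBS96 class: when the reference base is a purine (A/G),
#' the mutation and its flanks are reverse-complemented before classification.
#' The reference base in the FASTA must match each key's `ref` allele.
#'
#' @param keys A data frame with columns `chrom`, `pos` (1-based), `ref`, `alt`.
#' @param reference A named [Biostrings::DNAStringSet] (names are contigs), or
#'   the path to a FASTA file.
#' @return `keys` with added columns `context` (reference-strand trinucleotide),
#'   `sbs96_class` (integer 0..95, `NA` when a flanking base is `N`) and
#'   `sbs96_label`. Keys with undefined class are reported via a message.
#' @export
sbs96_context <- function(keys, reference) {
  reference <- as_reference(reference)
  keys <- as_tibble(keys)
  if (nrow(keys) == 0) {
    return(mutate(keys, context = character(0), sbs96_class = integer(0),
                  sbs96_label = character(0)))
  }
  missing_contig <- setdiff(unique(keys$chrom), names(reference))
  if (length(missing_contig) > 0) {
    abort(paste0("contig absent from reference: ",
                 paste(missing_contig, collapse = ", ")))
  }
  widths <- setNames(Biostrings::width(reference), names(reference))
  if (any(keys$pos < 2 | keys$pos > widths[keys$chrom] - 1)) {
    abort("variant position too close to a contig end to resolve context")
  }
  ctx <- unname(as.character(Biostrings::subseq(
    reference[keys$chrom], start = keys$pos - 1L, end = keys$pos + 1L)))
  ref_base <- substr(ctx, 2, 2)
  bad <- ref_base != keys$ref
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf(
      "reference mismatch at %s:%d: reference has %s but key has ref %s",
      keys$chrom[i], keys$pos[i], ref_base[i], keys$ref[i]))
  }

  cat96 <- sbs96_catalog()
  # collapse to pyrimidine strand
  flip <- keys$ref %in% c("A", "G")
  ctx_p <- ifelse(flip, revcomp_chr(ctx), ctx)
  alt_p <- ifelse(flip, unname(COMPLEMENT[keys$alt]), keys$alt)
  lab <- paste0(substr(ctx_p, 1, 1), "[", substr(ctx_p, 2, 2), ">", alt_p, "]",
                substr(ctx_p, 3, 3))
  cls <- cat96$class[match(lab, cat96$label)]
  n_undef <- sum(is.na(cls))
  if (n_undef > 0) {
    inform(sprintf("%d variant(s) with N in context excluded from SBS96 classification",
                   n_undef))
  }
  mutate(keys, context = ctx,
         sbs96_class = as.integer(cls),
         sbs96_label = ifelse(is.na(cls), NA_character_, lab))
}

as_reference <- function(reference) {
  if (inherits(reference, "DNAStringSet")) return(reference)
  if (is.character(reference) && length(reference) == 1) {
    if (!file.exists(reference)) abort(paste0("reference FASTA not found: ", reference))
    ref <- Biostrings::readDNAStringSet(reference)
    names(ref) <- sub("\\s.*$", "", names(ref))
    return(ref)
  }
  abort("`reference` must be a DNAStringSet or a FASTA path")
}
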