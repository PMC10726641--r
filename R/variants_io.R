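#' Parse one cell's VCF into a tidy table of calls
#'
#' Reads a per-cell VCF 4.x file produced by one of the two caller pipelines
#' and normalizes it into one row per biallelic SNV observation. Multi-allelic
#' records are split into per-ALT calls with alt-specific allele depths and
#' genotype likelihoods; indels, MNVs and symbolic alleles are skipped and
#' counted. For the secondary caller (`caller = "S"`) only records whose
#' FILTER column is PASS are retained, mirroring that caller's own default
#' filtering.
#'
#' @param path Path to a VCF file (plain or gzip-compressed).
#' @param caller `"G"` for the primary (GATK-style) pipeline, whose INFO/FORMAT
#'   fields carry FS, QD and PL, or `"S"` for the secondary (Strelka-style)
#'   pipeline.
#' @param cell_id Cell identifier attached to every call.
#' @return A tibble with one row per call and columns `chrom`, `pos`, `ref`,
#'   `alt`, `cell_id`, `caller`, `dp`, `ad_ref`, `ad_alt`, `vaf`, `qual`,
#'   `pl_1`, `pl_2`, `pl_3` (min-normalized Phred genotype likelihoods), `fs`,
#'   `qd`, `read_pos_bias`, `pass_flag`. The number of skipped non-SNV
#'   (record, allele) pairs is stored in attribute `"n_skipped"`.
#' @export
parse_cell_vcf <- function(path, caller = c("G", "S"), cell_id) {
  caller <- match.arg(caller)
  if (!file.exists(path)) abort(paste0("VCF file not found: ", path))
  if (n_vcf_records(path) == 0) {
    out <- empty_calls()
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  filt <- fix[, "FILTER"]
  pass <- is.na(filt) | filt %in% c("PASS", ".")
  keep <- if (caller == "S") pass else rep(TRUE, nrow(fix))

  has_gt <- ncol(vcf@gt) >= 2
  fmt_dp <- if (has_gt) suppressWarnings(as.numeric(vcfR::extract.gt(vcf, "DP")[, 1])) else rep(NA_real_, nrow(fix))
  fmt_ad <- if (has_gt) vcfR::extract.gt(vcf, "AD")[, 1] else rep(NA_character_, nrow(fix))
  fmt_pl <- if (has_gt) vcfR::extract.gt(vcf, "PL")[, 1] else rep(NA_character_, nrow(fix))
  info_dp <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "DP")))
  fs <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "FS")))
  qd <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "QD")))
  rpb <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "ReadPosRankSum")))
  dp <- ifelse(is.na(fmt_dp), info_dp, fmt_dp)
  if (all(is.na(dp))) {
    abort(paste0("VCF lacks the required DP field (FORMAT or INFO): ", path))
  }
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))

  # expand multi-allelic records to one row per (record, alt)
  bases <- c("A", "C", "G", "T")
  alts_list <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alts_list)
  rec <- rep(seq_len(nrow(fix)), n_alt)
  j <- sequence(n_alt)
  ref_v <- fix[rec, "REF"]
  alt_v <- unlist(alts_list)
  is_snv <- nchar(ref_v) == 1 & nchar(alt_v) == 1 &
    ref_v %in% bases & alt_v %in% bases
  n_skipped <- sum(keep[rec] & !is_snv)
  sel <- keep[rec] & is_snv
  rec <- rec[sel]; j <- j[sel]; ref_v <- ref_v[sel]; alt_v <- alt_v[sel]
  if (length(rec) == 0) {
    out <- empty_calls()
    attr(out, "n_skipped") <- n_skipped
    return(out)
  }

  nth_num <- function(strings, k) {
    # k-th comma-separated numeric element of each string (NA when absent)
    lst <- strsplit(strings, ",", fixed = TRUE)
    suppressWarnings(as.numeric(vapply(seq_along(lst), function(i) {
      v <- lst[[i]]
      if (!is.na(k[i]) && length(v) >= k[i]) v[k[i]] else NA_character_
    }, character(1))))
  }
  ad_ref <- nth_num(fmt_ad[rec], rep(1L, length(rec)))
  ad_alt <- nth_num(fmt_ad[rec], j + 1L)
  # PL indices of the (0/0, 0/j, j/j) genotypes for alt j
  pl_1 <- nth_num(fmt_pl[rec], rep(1L, length(rec)))
  pl_2 <- nth_num(fmt_pl[rec], (j * (j + 1L)) %/% 2L + 1L)
  pl_3 <- nth_num(fmt_pl[rec], (j * (j + 1L)) %/% 2L + j + 1L)
  pl_min <- pmin(pl_1, pl_2, pl_3)

  out <- tibble(
    chrom = unname(fix[rec, "CHROM"]), pos = as.integer(fix[rec, "POS"]),
    ref = unname(ref_v), alt = unname(alt_v), cell_id = cell_id,
    caller = caller, dp = dp[rec], ad_ref = ad_ref, ad_alt = ad_alt,
    vaf = ifelse(!is.na(dp[rec]) & dp[rec] > 0, ad_alt / dp[rec], NA_real_),
    qual = qual[rec], pl_1 = pl_1 - pl_min, pl_2 = pl_2 - pl_min,
    pl_3 = pl_3 - pl_min, fs = fs[rec], qd = qd[rec],
    read_pos_bias = rpb[rec], pass_flag = pass[rec]
  ) |> arrange_keys()
  attr(out, "n_skipped") <- n_skipped
  out
}

empty_calls <- function() {
  tibble(chrom = character(), pos = integer(), ref = character(),
         alt = character(), cell_id = character(), caller = character(),
         dp = numeric(), ad_ref = numeric(), ad_alt = numeric(),
         vaf = numeric(), qual = numeric(), pl_1 = numeric(), pl_2 = numeric(),
         pl_3 = numeric(), fs = numeric(), qd = numeric(),
         read_pos_bias = numeric(), pass_flag = logical())
}

n_vcf_records <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  n <- 0L
  repeat {
    chunk <- readLines(con, n = 5000L)
    if (length(chunk) == 0) break
    n <- n + sum(!startsWith(chunk, "#") & nzchar(chunk))
  }
  n
}

#' Load an RNA-editing, germline, or truth site list
#'
#' Accepts a VCF (only SNV records are used) or a TSV with columns
#' `chrom`, `pos` and optionally `ref`, `alt` (with or without a header line).
#' Editing databases are site-level, so `kind = "editing"` keeps only
#' `(chrom, pos)`; all other kinds keep the full variant key. Duplicates are
#' collapsed.
#'
#' @param path Path to a VCF or TSV file (gzip allowed).
#' @param kind One of `"editing"`, `"germline_population"`,
#'   `"germline_matched_normal"`, `"exome_truth"`.
#' @return A tibble of unique sites (`chrom`, `pos` and, unless
#'   `kind = "editing"`, `ref`, `alt`) with attribute `"kind"`.
#' @export
load_site_list <- function(path, kind = c("editing", "germline_population",
                                          "germline_matched_normal", "exome_truth")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(paste0("site list not found: ", path))
  first <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path, n = 1L)
  is_vcf <- length(first) > 0 && startsWith(first, "##fileformat=VCF")
  if (is_vcf) {
    if (n_vcf_records(path) == 0) {
      sites <- tibble(chrom = character(), pos = integer(),
                      ref = character(), alt = character())
    } else {
      vcf <- vcfR::read.vcfR(path, verbose = FALSE)
      fix <- vcfR::getFIX(vcf)
      if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
      sites <- tibble(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"]) |>
        tidyr::separate_longer_delim("alt", ",") |>
        filter(nchar(.data$ref) == 1, nchar(.data$alt) == 1,
               .data$ref %in% c("A", "C", "G", "T"),
               .data$alt %in% c("A", "C", "G", "T"))
    }
  } else {
    lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines) == 0) {
      sites <- tibble(chrom = character(), pos = integer(),
                      ref = character(), alt = character())
    } else {
      fields <- strsplit(lines, "\t", fixed = TRUE)
      has_header <- is.na(suppressWarnings(as.integer(fields[[1]][2])))
      if (has_header) { lines <- lines[-1]; fields <- fields[-1] }
      pos <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 2)))
      if (any(is.na(pos))) {
        bad <- which(is.na(pos))[1] + has_header
        abort(sprintf("malformed site-list row at line %d of %s", bad, path))
      }
      sites <- tibble(
        chrom = vapply(fields, `[`, character(1), 1), pos = pos,
        ref = vapply(fields, function(f) if (length(f) >= 4) f[3] else NA_character_, character(1)),
        alt = vapply(fields, function(f) if (length(f) >= 4) f[4] else NA_character_, character(1))
      )
    }
  }
  sites <- if (kind == "editing") distinct(sites[, c("chrom", "pos")]) else distinct(sites)
  if (nrow(sites) == 0) warn(paste0("site list is empty: ", path))
  out <- arrange(sites, .data$chrom, .data$pos)
  attr(out, "kind") <- kind
  out
}

#' Read exon (or gene) intervals from a BED file
#'
#' BED intervals are 0-based half-open on disk and converted to 1-based
#' closed coordinates on import. Overlapping exon intervals are merged.
#'
#' @param path Path to a BED file.
#' @param merge Merge overlapping intervals (default `TRUE`; set `FALSE` for
#'   gene spans whose names must be preserved).
#' @return A [GenomicRanges::GRanges] object.
#' @export
read_bed <- function(path, merge = TRUE) {
  if (!file.exists(path)) abort(paste0("BED file not found: ", path))
  gr <- rtracklayer::import(path, format = "BED")
  if (merge) GenomicRanges::reduce(gr) else gr
}

# logical: is each key's position inside any interval of `gr`?
keys_in_ranges <- function(keys, gr) {
  if (nrow(keys) == 0) return(logical(0))
  q <- GenomicRanges::GRanges(keys$chrom, IRanges::IRanges(keys$pos, keys$pos))
  IRanges::overlapsAny(q, gr)
}

#' Write variant keys as a minimal sites-only VCF
#'
#' @param keys Data frame with `chrom`, `pos`, `ref`, `alt` (extra columns
#'   ignored).
#' @param path Output path.
#' @param contig_lengths Optional named integer vector for `##contig` header
#'   lines.
#' @return `path`, invisibly.
#' @export
write_sites_vcf <- function(keys, path, contig_lengths = NULL) {
  keys <- arrange_keys(distinct(as_tibble(keys)[, KEY_COLS]))
  header <- c("##fileformat=VCFv4.2", "##source=scresa")
  if (!is.null(contig_lengths)) {
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>",
                                names(contig_lengths), contig_lengths))
  }
  header <- c(header, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", keys$chrom, keys$pos,
                  keys$ref, keys$alt)
  writeLines(c(header, body), path)
  invisible(path)
}

fmt_num <- function(x, digits = 4) {
  out <- sub("0+$", "", sub("\\.$", "", sprintf(paste0("%.", digits, "f"), x)))
  out <- sub("\\.$", "", out)
  ifelse(is.na(x), ".", out)
}

#' Write one cell's calls as a caller-style VCF
#'
#' Emits the per-cell VCF flavour of either pipeline: the primary caller
#' (`"G"`) writes QUAL, INFO `DP;FS;QD` and FORMAT `GT:AD:DP:PL`; the
#' secondary caller (`"S"`) writes a PASS-filtered file with FORMAT
#' `GT:AD:DP`. Used by the cohort simulator and for round-tripping calls.
#'
#' @param calls Tibble of calls for a single cell (schema of
#'   [parse_cell_vcf()]).
#' @param path Output path.
#' @param caller `"G"` or `"S"`.
#' @param contig_lengths Optional named vector for `##contig` lines.
#' @param sample_name Sample column name (defaults to the cell id).
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, path, caller = c("G", "S"),
                            contig_lengths = NULL, sample_name = NULL) {
  caller <- match.arg(caller)
  calls <- arrange_keys(as_tibble(calls))
  sample_name <- sample_name %||% (if (nrow(calls)) calls$cell_id[1] else "sample")
  header <- c("##fileformat=VCFv4.2",
              sprintf("##source=scresa-caller-%s", caller))
  if (!is.null(contig_lengths)) {
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>",
                                names(contig_lengths), contig_lengths))
  }
  header <- c(header,
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">")
  if (caller == "G") {
    header <- c(header,
      "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Phred strand bias\">",
      "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
      "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred genotype likelihoods\">")
  }
  header <- c(header, paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                             sample_name))
  if (nrow(calls) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  if (caller == "G") {
    info <- sprintf("DP=%d;FS=%s;QD=%s", as.integer(calls$dp),
                    fmt_num(calls$fs, 2), fmt_num(calls$qd, 2))
    gt <- sprintf("0/1:%d,%d:%d:%d,%d,%d", as.integer(calls$ad_ref),
                  as.integer(calls$ad_alt), as.integer(calls$dp),
                  as.integer(calls$pl_1), as.integer(calls$pl_2),
                  as.integer(calls$pl_3))
    fmt <- "GT:AD:DP:PL"
  } else {
    info <- sprintf("DP=%d", as.integer(calls$dp))
    gt <- sprintf("0/1:%d,%d:%d", as.integer(calls$ad_ref),
                  as.integer(calls$ad_alt), as.integer(calls$dp))
    fmt <- "GT:AD:DP"
  }
  body <- sprintf("%s\t%d\t.\t%s\t%s\t%s\tPASS\t%s\t%s\t%s",
                  calls$chrom, calls$pos, calls$ref, calls$alt,
                  fmt_num(calls$qual, 2), info, fmt, gt)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a cohort manifest
#'
#' A manifest is a TSV with header columns `cell_id`, `vcf_g`, `vcf_s` and
#' optionally `stage`. Relative VCF paths are resolved against the manifest's
#' directory. Rows are sorted by `cell_id` so results never depend on manifest
#' row order.
#'
#' @param path Path to the manifest TSV.
#' @return A tibble with columns `cell_id`, `vcf_g`, `vcf_s` and (if present)
#'   `stage`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(paste0("manifest not found: ", path))
  m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("cell_id", "vcf_g", "vcf_s")
  if (!all(need %in% names(m))) {
    abort("manifest must have columns cell_id, vcf_g, vcf_s")
  }
  base <- dirname(path)
  fix_path <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  m |>
    mutate(vcf_g = fix_path(.data$vcf_g), vcf_s = fix_path(.data$vcf_s)) |>
    arrange(.data$cell_id)
}
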