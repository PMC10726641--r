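# In-code fixtures and independent brute-force oracles used across the suite.

make_reference <- function(seq) {
  ref <- Biostrings::DNAStringSet(seq)
  names(ref) <- "chr1"
  ref
}

write_vcf <- function(path, body, format_cols = TRUE, extra_header = character()) {
  header <- c("##fileformat=VCFv4.2",
              "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
              "##INFO=<ID=FS,Number=1,Type=Float,Description=\"f\">",
              "##INFO=<ID=QD,Number=1,Type=Float,Description=\"q\">",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
              "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
              "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"p\">",
              extra_header,
              paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
                     if (format_cols) "\tFORMAT\ts1"))
  writeLines(c(header, body), path)
  path
}

# random cohort of labeled-ready calls (set + quality fields), for oracle tests
random_cohort_calls <- function(n_cells, n_keys, seed) {
  set.seed(seed)
  cells <- sprintf("c%02d", seq_len(n_cells))
  bases <- c("A", "C", "G", "T")
  keys <- tibble::tibble(
    chrom = "chr1", pos = sort(sample(1000:9999, n_keys)),
    ref = sample(bases, n_keys, replace = TRUE)
  )
  keys$alt <- vapply(keys$ref, function(r) sample(setdiff(bases, r), 1), "")
  rows <- lapply(seq_len(n_keys), function(i) {
    in_cells <- sample(cells, sample.int(n_cells, 1))
    n <- length(in_cells)
    tibble::tibble(
      chrom = keys$chrom[i], pos = keys$pos[i], ref = keys$ref[i],
      alt = keys$alt[i], cell_id = in_cells, caller = "G",
      dp = sample(0:12, n, replace = TRUE),
      ad_alt = sample(0:4, n, replace = TRUE),
      qual = runif(n, 1, 200),
      qd = ifelse(runif(n) < 0.2, NA_real_, runif(n, 0, 10)),
      fs = ifelse(runif(n) < 0.2, NA_real_, runif(n, 0, 60)),
      set = sample(c("A", "B"), n, replace = TRUE, prob = c(0.6, 0.4))
    )
  })
  calls <- dplyr::bind_rows(rows)
  calls$ad_alt <- pmin(calls$ad_alt, calls$dp)
  calls$ad_ref <- calls$dp - calls$ad_alt
  calls$vaf <- ifelse(calls$dp > 0, calls$ad_alt / calls$dp, NA_real_)
  calls$pl_1 <- round(calls$qual); calls$pl_2 <- 0
  calls$pl_3 <- round(3 * calls$ad_ref + 10)
  calls$read_pos_bias <- NA_real_
  calls$pass_flag <- TRUE
  calls
}

# direct, unoptimized reimplementation of the labeling rules
oracle_labels <- function(calls, cfg, n_cells) {
  L <- max(cfg$recurrence_floor, ceiling(cfg$recurrence_lower_frac * n_cells))
  U <- floor(cfg$recurrence_upper_frac * n_cells)
  ids <- unique(paste(calls$chrom, calls$pos, calls$ref, calls$alt))
  out <- character(length(ids))
  for (i in seq_along(ids)) {
    sub <- calls[paste(calls$chrom, calls$pos, calls$ref, calls$alt) == ids[i], ]
    rec <- length(unique(sub$cell_id))
    qp <- logical(nrow(sub))
    for (r in seq_len(nrow(sub))) {
      qp[r] <- !is.na(sub$dp[r]) && sub$dp[r] >= cfg$min_depth &&
        (is.na(sub$qd[r]) || sub$qd[r] >= cfg$qd_min) &&
        (is.na(sub$fs[r]) || sub$fs[r] <= cfg$fs_max) &&
        !is.na(sub$ad_alt[r]) && sub$ad_alt[r] >= 1
    }
    out[i] <- if (rec > U) "removed"
      else if (any(sub$set == "A" & qp) && rec >= L) "positive"
      else if (all(sub$set == "B") && !any(qp) &&
               rec <= cfg$negative_max_recurrence) "negative"
      else "unsure"
  }
  stats::setNames(out, ids)
}

# pair-enumeration AUC oracle
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# independent SBS96 classifier built from first principles
oracle_sbs96 <- function(five, ref, three, alt) {
  comp <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]
  if (ref %in% c("A", "G")) {
    tmp <- comp(five); five <- comp(three); three <- tmp
    ref <- comp(ref); alt <- comp(alt)
  }
  types <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  ti <- match(paste0(ref, ">", alt), types) - 1L
  16L * ti + 4L * (match(five, bases) - 1L) + (match(three, bases) - 1L)
}

# uniform integer in [lo, hi] avoiding sample()'s scalar expansion
rint <- function(lo, hi) if (lo >= hi) lo else sample(lo:hi, 1)

# exact combinatorial upper-tail hypergeometric
oracle_hyper_upper <- function(k, K, N, n) {
  hi <- min(n, K)
  if (k > hi) return(0)
  sum(vapply(k:hi, function(i) {
    choose(K, i) * choose(N - K, n - i) / choose(N, n)
  }, numeric(1)))
}

# synthetic logistic labeled rows over the quality feature block
synth_logistic_rows <- function(n, seed, informative = TRUE) {
  set.seed(seed)
  x <- matrix(rnorm(n * 8), n, 8,
              dimnames = list(NULL, c("qual", "dp", "vaf", "pl_1", "pl_2",
                                      "pl_3", "ad_ref", "ad_alt")))
  eta <- if (informative) 4 * x[, "vaf"] + 2 * x[, "qual"] - 1.5 * x[, "dp"]
         else rep(0, n)
  y <- rbinom(n, 1, stats::plogis(eta))
  mt <- t(stats::rmultinom(n, 1, rep(1 / 6, 6)))
  colnames(mt) <- paste0("mt_", 1:6)
  list(quality = x, sequence = mt, y = y)
}
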