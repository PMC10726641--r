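toy_exons <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50, 500))

toy_call <- function(pos, cell = "c1", set = "B", dp = 10, qd = 5, fs = 1,
                     ad_alt = 4, ref = "C", alt = "T") {
  tibble::tibble(chrom = "chr1", pos = pos, ref = ref, alt = alt,
                 cell_id = cell, caller = "G", dp = dp, ad_ref = dp - ad_alt,
                 ad_alt = ad_alt, vaf = ad_alt / dp, qual = 100,
                 pl_1 = 100, pl_2 = 0, pl_3 = 30, fs = fs, qd = qd,
                 read_pos_bias = NA_real_, pass_flag = TRUE, set = set)
}

test_that("annotation filter removes non-exonic, editing and germline keys in order", {
  calls <- dplyr::bind_rows(
    toy_call(10),    # outside exons
    toy_call(100),   # editing site
    toy_call(200),   # germline-listed
    toy_call(300), toy_call(400))
  editing <- tibble::tibble(chrom = "chr1", pos = 100L)
  germline <- tibble::tibble(chrom = "chr1", pos = 200L, ref = "C", alt = "T")
  res <- annotation_filter(calls, toy_exons, editing, germline)
  expect_equal(sort(res$kept$pos), c(300, 400))
  expect_equal(res$ledger, c(non_exonic = 1L, editing = 1L, germline_list = 1L))
  # a key in both the editing and germline lists is removed as editing:
  # the first matching reason in the stated order wins
  both <- annotation_filter(calls, toy_exons,
                            tibble::tibble(chrom = "chr1", pos = c(100L, 200L)),
                            germline)
  expect_equal(both$removed$reason[both$removed$pos == 200], "editing")
  expect_error(annotation_filter(calls, GenomicRanges::GRanges(), editing, germline),
               "empty")
  expect_warning(annotation_filter(calls, toy_exons, editing, NULL), "germline")
})

test_that("the quality predicate enforces depth, QD, FS and alt support", {
  cfg <- resa_config()
  cases <- tibble::tibble(
    dp = c(3, 2, 10, 10, 10, 10, 3),
    qd = c(5, 8, 1.9, NA, 5, 5, 5),
    fs = c(10, 1, 1, 1, 31, NA, 10),
    ad_alt = c(2, 2, 2, 2, 2, 2, 0)
  )
  expect_equal(quality_pass(cases, cfg),
               c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE))
})

test_that("dual-caller set assignment is per-cell set algebra", {
  g <- dplyr::bind_rows(toy_call(100), toy_call(200), toy_call(300))
  s <- dplyr::bind_rows(toy_call(200), toy_call(300), toy_call(999))
  res <- assign_sets(g, s)
  expect_equal(res$set[order(res$pos)], c("B", "A", "A"))
  expect_equal(nrow(res), 3)  # the caller-S-only key is ignored
  expect_warning(assign_sets(toy_call(100, cell = "lonely"), s), "set B")
})

test_that("recurrence counts distinct cells and matches a brute-force scan", {
  calls <- dplyr::bind_rows(
    toy_call(100, "c1"), toy_call(100, "c2"), toy_call(100, "c2"),
    toy_call(100, "c3"), toy_call(200, "c1"))
  rec <- recurrence_counts(calls)
  expect_equal(rec$recurrence[rec$pos == 100], 3)
  expect_equal(rec$recurrence[rec$pos == 200], 1)

  for (seed in 1:5) {
    cohort <- random_cohort_calls(n_cells = 20, n_keys = 50, seed = seed)
    rec <- recurrence_counts(cohort)
    ids <- paste(cohort$chrom, cohort$pos, cohort$ref, cohort$alt)
    brute <- vapply(paste(rec$chrom, rec$pos, rec$ref, rec$alt), function(id) {
      length(unique(cohort$cell_id[ids == id]))
    }, integer(1))
    expect_equal(rec$recurrence, unname(brute))
  }
})

test_that("recurrence bounds follow the ceil/floor convention", {
  cfg <- resa_config()
  expect_equal(recurrence_bounds(cfg, 30), list(L = 3L, U = 24L))
  expect_equal(recurrence_bounds(cfg, 100), list(L = 10L, U = 80L))
  expect_equal(recurrence_bounds(cfg, 12), list(L = 3L, U = 9L))
  expect_error(resa_config(n_cells = 3), "bounds")
})

test_that("cohort labeling applies the positive/negative/unsure rules", {
  cfg <- resa_config(n_cells = 30)
  # positive: 5 quality-passing set-A cells in a 30-cell cohort (L=3, U=24)
  pos_calls <- dplyr::bind_rows(lapply(1:5, function(i) {
    toy_call(100, sprintf("c%02d", i), set = "A")
  }))
  # over-recurrent: 25 of 30 cells
  over_calls <- dplyr::bind_rows(lapply(1:25, function(i) {
    toy_call(200, sprintf("c%02d", i), set = "A")
  }))
  # negative: one set-B quality-failing call; unsure: same but quality-passing
  neg_call <- toy_call(300, "c01", set = "B", dp = 2)
  uns_call <- toy_call(400, "c01", set = "B")
  filler <- dplyr::bind_rows(lapply(6:30, function(i) {
    toy_call(500, sprintf("c%02d", i), set = "B", dp = 2)
  }))
  lab <- label_cohort(dplyr::bind_rows(pos_calls, over_calls, neg_call,
                                       uns_call, filler), cfg)
  labs <- setNames(lab$labels$label, lab$labels$pos)
  expect_equal(unname(labs[c("100", "200", "300", "400")]),
               c("positive", "removed", "negative", "unsure"))
  expect_equal(lab$labels$reason[lab$labels$pos == 200], "over_recurrent")
  expect_error(label_cohort(pos_calls, resa_config(n_cells = 99)), "99")
})

test_that("labeling agrees key-for-key with a direct rule reimplementation", {
  for (seed in 1:12) {
    n_cells <- sample(8:20, 1)
    cohort <- random_cohort_calls(n_cells, n_keys = sample(30:100, 1), seed)
    cfg <- resa_config()
    lab <- label_cohort(cohort, cfg)
    got <- setNames(lab$labels$label,
                    paste(lab$labels$chrom, lab$labels$pos, lab$labels$ref,
                          lab$labels$alt))
    expected <- oracle_labels(cohort, cfg, length(unique(cohort$cell_id)))
    expect_equal(got[names(expected)], expected)
    # partition invariant
    expect_equal(nrow(lab$labels),
                 nrow(dplyr::distinct(cohort[, c("chrom", "pos", "ref", "alt")])))
  }
})

test_that("raising the lower recurrence bound never adds positives", {
  cohort <- random_cohort_calls(15, 80, seed = 99)
  pos_at <- function(frac) {
    lab <- label_cohort(cohort, resa_config(recurrence_lower_frac = frac))
    lab$labels[lab$labels$label == "positive", c("chrom", "pos", "ref", "alt")]
  }
  loose <- pos_at(0.10); strict <- pos_at(0.30)
  expect_true(all(paste(strict$pos, strict$alt) %in% paste(loose$pos, loose$alt)))

  removed_at <- function(frac) {
    lab <- label_cohort(cohort, resa_config(recurrence_upper_frac = frac))
    lab$labels[lab$labels$label == "removed", c("pos", "alt")]
  }
  hi <- removed_at(0.80); lo <- removed_at(0.50)
  expect_true(all(paste(hi$pos, hi$alt) %in% paste(lo$pos, lo$alt)))
})

test_that("labeling is deterministic and independent of call order", {
  cohort <- random_cohort_calls(12, 40, seed = 3)
  lab1 <- label_cohort(cohort, resa_config())
  lab2 <- label_cohort(cohort[sample(nrow(cohort)), ], resa_config())
  expect_equal(lab1$labels, lab2$labels)
})

test_that("germline-listed keys are always removed with the germline reason", {
  calls <- dplyr::bind_rows(lapply(sprintf("c%d", 1:5), function(cell) {
    dplyr::bind_rows(toy_call(100, cell), toy_call(200, cell),
                     toy_call(300, cell))
  }))
  germ <- tibble::tibble(chrom = "chr1", pos = c(100L, 300L),
                         ref = "C", alt = "T")
  lab <- resa_label(calls, calls, toy_exons, editing = NULL, germline = germ,
                    cfg = resa_config())
  g <- lab$labels[lab$labels$pos %in% c(100, 300), ]
  expect_true(all(g$label == "removed"))
  expect_true(all(g$reason == "germline_list"))
})
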