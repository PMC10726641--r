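test_that("a biallelic SNV record maps field-for-field onto a call", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(path, "chr1\t100\t.\tC\tT\t84.3\tPASS\tDP=10;FS=1.2;QD=8.4\tGT:AD:DP:PL\t0/1:6,4:10:84,0,120")
  calls <- parse_cell_vcf(path, caller = "G", cell_id = "c1")
  expect_equal(nrow(calls), 1)
  expect_equal(calls$chrom, "chr1")
  expect_equal(calls$pos, 100L)
  expect_equal(calls$ref, "C")
  expect_equal(calls$alt, "T")
  expect_equal(calls$dp, 10)
  expect_equal(calls$ad_ref, 6)
  expect_equal(calls$ad_alt, 4)
  expect_equal(calls$vaf, 0.4)
  expect_equal(calls$qual, 84.3)
  expect_equal(c(calls$pl_1, calls$pl_2, calls$pl_3), c(84, 0, 120))
  expect_equal(calls$fs, 1.2)
  expect_equal(calls$qd, 8.4)
  expect_true(calls$pass_flag)
  expect_equal(attr(calls, "n_skipped"), 0L)
})

test_that("multi-allelic records split into per-alt calls conserving alleles", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(path, "chr1\t100\t.\tC\tT,G\t50\tPASS\tDP=10\tGT:AD:DP:PL\t1/2:5,3,2:10:90,40,30,60,0,70")
  calls <- parse_cell_vcf(path, caller = "G", cell_id = "c1")
  expect_equal(nrow(calls), 2)
  expect_setequal(calls$alt, c("T", "G"))
  expect_equal(calls$ad_alt[calls$alt == "T"], 3)
  expect_equal(calls$ad_alt[calls$alt == "G"], 2)
  expect_equal(unique(calls$dp), 10)
  expect_equal(unique(calls$ad_ref), 5)
  # PL triple for alt 1 is entries (1,2,3): (90,40,30) -> min-normalized (60,10,0)
  t_row <- calls[calls$alt == "T", ]
  expect_equal(c(t_row$pl_1, t_row$pl_2, t_row$pl_3), c(60, 10, 0))
  # alt 2 uses entries (1,4,6): (90,60,70) -> (30,0,10)
  g_row <- calls[calls$alt == "G", ]
  expect_equal(c(g_row$pl_1, g_row$pl_2, g_row$pl_3), c(30, 0, 10))
})

test_that("indels are skipped with a logged count and caller S honours FILTER", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(path, c(
    "chr1\t100\t.\tCT\tC\t50\tPASS\tDP=10\tGT:AD:DP\t0/1:6,4:10",
    "chr1\t200\t.\tA\tG\t60\tPASS\tDP=12\tGT:AD:DP\t0/1:8,4:12",
    "chr1\t300\t.\tC\tT\t70\tLowQual\tDP=9\tGT:AD:DP\t0/1:5,4:9"))
  g <- parse_cell_vcf(path, caller = "G", cell_id = "c1")
  expect_equal(nrow(g), 2)          # indel dropped, LowQual kept for caller G
  expect_equal(attr(g, "n_skipped"), 1L)
  expect_false(g$pass_flag[g$pos == 300])
  s <- parse_cell_vcf(path, caller = "S", cell_id = "c1")
  expect_equal(s$pos, 200L)         # only the PASS SNV survives for caller S
})

test_that("a VCF without any DP field is a fatal format error", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(path, "chr1\t100\t.\tC\tT\t50\tPASS\tNS=3\tGT:AD\t0/1:6,4")
  expect_error(parse_cell_vcf(path, "G", "c1"), "DP")
  expect_error(parse_cell_vcf(tempfile(), "G", "c1"), "not found")
})

test_that("calls written as VCF round-trip through the parser", {
  calls <- parse_cell_vcf(
    write_vcf(withr::local_tempfile(fileext = ".vcf"), c(
      "chr1\t120\t.\tG\tA\t90.25\tPASS\tDP=14;FS=2.5;QD=6.75\tGT:AD:DP:PL\t0/1:9,5:14:90,0,130",
      "chr2\t77\t.\tT\tC\t33.5\tPASS\tDP=5;FS=0.1;QD=4.1\tGT:AD:DP:PL\t0/1:2,3:5:33,0,16")),
    caller = "G", cell_id = "cellX")
  out <- withr::local_tempfile(fileext = ".vcf")
  write_calls_vcf(calls, out, caller = "G")
  back <- parse_cell_vcf(out, caller = "G", cell_id = "cellX")
  expect_equal(back, calls, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("site lists collapse duplicates and obey kind-specific matching", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t100", "chr1\t100", "chr2\t5"), tsv)
  ed <- load_site_list(tsv, "editing")
  expect_equal(nrow(ed), 2)
  expect_named(ed, c("chrom", "pos"))

  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(vcf, c("chr1\t10\t.\tA\tG\t.\tPASS\t.",
                   "chr1\t20\t.\tC\tT\t.\tPASS\t.",
                   "chr1\t30\t.\tG\tC\t.\tPASS\t.",
                   "chr1\t40\t.\tGT\tG\t.\tPASS\t."), format_cols = FALSE)
  germ <- load_site_list(vcf, "germline_population")
  expect_equal(nrow(germ), 3)                      # the indel row is dropped
  expect_named(germ, c("chrom", "pos", "ref", "alt"))

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_warning(e <- load_site_list(empty, "editing"), "empty")
  expect_equal(nrow(e), 0)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos", "chr1\toops"), bad)
  expect_error(load_site_list(bad, "editing"), "line 2")
  expect_error(load_site_list(tempfile(), "editing"), "not found")
})

test_that("trinucleotide context resolves the canonical SBS96 class", {
  ref <- make_reference(paste0(strrep("T", 98), "ACA", "TGT", strrep("T", 96)))
  # C at position 100 flanked by A/A: A[C>A]A is class 0
  k1 <- sbs96_context(tibble::tibble(chrom = "chr1", pos = 100L, ref = "C", alt = "A"), ref)
  expect_equal(k1$sbs96_class, 0L)
  expect_equal(k1$context, "ACA")
  # G at 103 flanked by T/T reverse-complements to A[C>A]A as well
  k2 <- sbs96_context(tibble::tibble(chrom = "chr1", pos = 103L, ref = "G", alt = "T"), ref)
  expect_equal(k2$sbs96_class, 0L)
  # reference mismatch is fatal and reports both bases
  expect_error(
    sbs96_context(tibble::tibble(chrom = "chr1", pos = 100L, ref = "A", alt = "G"), ref),
    "mismatch")
})

test_that("SBS96 classification is strand-collapse idempotent on random keys", {
  set.seed(7)
  bases <- c("A", "C", "G", "T")
  seq <- paste(sample(bases, 500, replace = TRUE), collapse = "")
  ref <- make_reference(seq)
  pos <- sample(2:499, 60)
  keys <- tibble::tibble(chrom = "chr1", pos = pos,
                         ref = vapply(pos, function(p) substr(seq, p, p), ""))
  keys$alt <- vapply(keys$ref, function(r) sample(setdiff(bases, r), 1), "")
  cls <- sbs96_context(keys, ref)$sbs96_class
  # independent first-principles classifier
  expected <- vapply(seq_len(nrow(keys)), function(i) {
    oracle_sbs96(substr(seq, pos[i] - 1, pos[i] - 1), keys$ref[i],
                 substr(seq, pos[i] + 1, pos[i] + 1), keys$alt[i])
  }, integer(1))
  expect_equal(cls, expected)
})
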