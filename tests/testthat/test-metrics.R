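test_that("truth-set evaluation counts and metrics are exact", {
  truth <- sprintf("chr1:%d:C:T", 1:16)
  expect_equal(evaluate_against_truth(truth[1:10], truth[1:10]),
               tibble::tibble(tp = 10L, fp = 0L, fn = 0L, precision = 1,
                              sensitivity = 1, f_half = 1))
  r <- evaluate_against_truth(c(truth[1:8], "chrX:1:A:G", "chrX:2:A:G"), truth)
  expect_equal(r$precision, 0.8)
  expect_equal(r$sensitivity, 0.5)
  r2 <- evaluate_against_truth(c("chrX:1:A:G"), truth)
  expect_equal(r2$precision, 0)
  expect_equal(r2$sensitivity, 0)
  expect_warning(r3 <- evaluate_against_truth(character(0), truth), "undefined")
  expect_true(is.na(r3$precision))
  expect_equal(r3$sensitivity, 0)
})

test_that("F0.5 follows the printed formula and weights precision", {
  expect_equal(f_half(1, 1), 1)
  expect_equal(f_half(0.8, 0.4), 1.25 * 0.32 / (0.2 + 0.4))
  expect_equal(f_half(0.8, 0.4), 2 / 3, tolerance = 1e-12)
  # identity on the diagonal
  p <- seq(0.05, 1, by = 0.05)
  expect_equal(f_half(p, p), p)
  # general F-beta oracle at beta = 0.5
  fbeta <- function(p, s, beta) (1 + beta^2) * p * s / (beta^2 * p + s)
  g <- expand.grid(p = seq(0.1, 1, 0.1), s = seq(0.1, 1, 0.1))
  expect_equal(f_half(g$p, g$s), fbeta(g$p, g$s, 0.5))
  # precision weighting: swapping a smaller precision in hurts
  asym <- subset(g, p < s)
  expect_true(all(f_half(asym$p, asym$s) < f_half(asym$s, asym$p)))
  expect_true(is.na(f_half(0, 0)))
})

test_that("the overlap coefficient matches its definition", {
  x <- letters[1:4]; y <- letters[3:9]
  expect_equal(overlap_coefficient(x, x), 1)
  expect_equal(overlap_coefficient(x, letters[10:12]), 0)
  expect_equal(overlap_coefficient(x, y), 2 / 4)
  expect_warning(o <- overlap_coefficient(character(0), x), "empty")
  expect_true(is.na(o))
})

test_that("spectra match a brute-force classifier and add under partition", {
  set.seed(13)
  bases <- c("A", "C", "G", "T")
  seq <- paste(sample(bases, 3000, replace = TRUE), collapse = "")
  ref <- make_reference(seq)
  pos <- sample(2:2999, 50)
  keys <- tibble::tibble(chrom = "chr1", pos = pos,
                         ref = vapply(pos, function(p) substr(seq, p, p), ""))
  keys$alt <- vapply(keys$ref, function(r) sample(setdiff(bases, r), 1), "")
  sp <- mutation_spectrum(keys, ref)
  expect_equal(sum(sp$count), 50)
  brute <- integer(96)
  for (i in seq_len(nrow(keys))) {
    cls <- oracle_sbs96(substr(seq, pos[i] - 1, pos[i] - 1), keys$ref[i],
                        substr(seq, pos[i] + 1, pos[i] + 1), keys$alt[i])
    brute[cls + 1] <- brute[cls + 1] + 1L
  }
  expect_equal(sp$count, brute)
  # additivity over a disjoint partition
  a <- mutation_spectrum(keys[1:20, ], ref)
  b <- mutation_spectrum(keys[21:50, ], ref)
  expect_equal(a$count + b$count, sp$count)
})

test_that("cosine similarity is scale invariant with the right extremes", {
  a <- c(rep(3, 48), rep(0, 48))
  b <- c(rep(0, 48), rep(5, 48))
  expect_equal(cosine_similarity(a, a), 1)
  expect_equal(cosine_similarity(a, b), 0)
  expect_equal(cosine_similarity(a, 3 * a), 1)
  expect_warning(z <- cosine_similarity(a, rep(0, 96)), "zero")
  expect_true(is.na(z))
})

test_that("hypergeometric enrichment matches exact enumeration", {
  carriers <- tibble::tibble(gene = "g1", stage = "s1", k = 4L)
  sizes <- tibble::tibble(stage = c("s1", "s2"), n = c(5L, 5L))
  res <- stage_enrichment(carriers, sizes)
  r1 <- res[res$stage == "s1", ]
  expect_equal(r1$p_value, 6 / 252, tolerance = 1e-12)  # C(4,4)C(6,1)/C(10,5)
  expect_true(r1$enriched)
  # K = 0 gives p = 1 everywhere
  res0 <- stage_enrichment(tibble::tibble(gene = "g0", stage = "s1", k = 0L), sizes)
  expect_true(all(res0$p_value == 1))
  expect_false(any(res0$enriched))
  # random small instances vs the combinatorial oracle, exact to 1e-12
  set.seed(41)
  for (i in 1:50) {
    N <- sample(4:12, 1)
    n1 <- rint(1, N - 1)
    K <- rint(0, N)
    k1 <- rint(max(0, K - (N - n1)), min(n1, K))
    res <- stage_enrichment(
      tibble::tibble(gene = "g", stage = c("a", "b"), k = c(k1, K - k1)),
      tibble::tibble(stage = c("a", "b"), n = c(n1, N - n1)))
    expect_equal(res$p_value[res$stage == "a"],
                 oracle_hyper_upper(k1, K, N, n1), tolerance = 1e-12)
  }
  expect_error(
    stage_enrichment(tibble::tibble(gene = "g", stage = "s1", k = 6L), sizes),
    "inconsistent")
})

test_that("carrier counting conserves totals across stages", {
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 500), c(499, 999)),
                                  name = c("geneA", "geneB"))
  calls <- tibble::tibble(chrom = "chr1", pos = c(10L, 20L, 600L, 700L, 10L),
                          ref = "C", alt = "T",
                          cell_id = c("c1", "c2", "c2", "c3", "c1"))
  stages <- tibble::tibble(cell_id = c("c1", "c2", "c3", "c4"),
                           stage = c("s1", "s1", "s2", "s2"))
  cc <- carrier_counts(calls, genes, stages)
  k_geneA <- cc$carriers$k[cc$carriers$gene == "geneA"]
  expect_equal(sum(k_geneA), 2)    # c1 counted once despite two variants
  expect_equal(sum(cc$stage_sizes$n), 4)
  res <- stage_enrichment(cc$carriers, cc$stage_sizes)
  conserved <- tapply(res$k, res$gene, sum)
  expect_equal(as.vector(conserved[c("geneA", "geneB")]), c(2, 2))
})
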