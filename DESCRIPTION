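Package: scresa
Title: High-Precision Expressed Somatic SNV Detection from Single-Cell RNA-Seq Variant Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects expressed somatic single-nucleotide variants de novo from
    full-length single-cell RNA-seq data, starting from per-cell variant calls
    produced by two independent caller pipelines. Implements annotation-based
    filtering (exonic regions, RNA-editing sites, germline lists), dual-caller
    consensus set construction, quality filtering, cross-cell recurrence
    bounding, and a positive/negative/unsure partition of candidate variants; a
    joint L1/L2 penalized logistic-regression classifier refines the unsure set.
    Includes evaluation against truth sets (precision, sensitivity, F0.5,
    overlap coefficient, AUC), SBS96 mutational-spectrum construction with
    cosine similarity, hypergeometric stage-enrichment testing, and a synthetic
    per-cell VCF cohort simulator with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    glmnet,
    jsonlite,
    vcfR,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
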