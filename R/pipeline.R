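#' Run the filtering-and-labeling pipeline on a cohort of per-cell VCFs
#'
#' File-level orchestrator: reads the manifest and every cell's caller pair,
#' applies annotation filtering (exons, editing sites, germline lists),
#' dual-caller set assignment, quality filtering and cross-cell recurrence
#' bounding, and partitions candidate keys into positive / negative / unsure /
#' removed. When `out_dir` is given it writes `positive.vcf`, `negative.vcf`,
#' `unsure.vcf`, `labels.tsv`, `calls.tsv` (per-call evidence, consumed by
#' [resa_refine()]) and `run_log.json`.
#'
#' @param manifest Path to the cohort manifest TSV ([read_manifest()]).
#' @param exons Path to the exon BED.
#' @param editing Path to the RNA-editing site list (TSV or VCF), or `NULL`.
#' @param germline Path(s) to germline site lists (population and/or matched
#'   normal), or `NULL`.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param cfg A [resa_config()].
#' @return The `resa_labeling` object, invisibly when writing.
#' @export
resa_run <- function(manifest, exons, editing = NULL, germline = NULL,
                     out_dir = NULL, cfg = resa_config()) {
  m <- read_manifest(manifest)
  calls_g <- purrr::pmap(m, function(cell_id, vcf_g, ...) {
    parse_cell_vcf(vcf_g, caller = "G", cell_id = cell_id)
  }) |> bind_rows()
  calls_s <- purrr::pmap(m, function(cell_id, vcf_s, ...) {
    parse_cell_vcf(vcf_s, caller = "S", cell_id = cell_id)
  }) |> bind_rows()
  exons_gr <- read_bed(exons)
  edit_sites <- if (!is.null(editing)) load_site_list(editing, "editing")
  germ_lists <- if (!is.null(germline)) {
    lapply(seq_along(germline), function(i) {
      kind <- if (i == 1) "germline_population" else "germline_matched_normal"
      load_site_list(germline[i], kind)
    })
  }
  lab <- resa_label(calls_g, calls_s, exons_gr, edit_sites, germ_lists, cfg)
  if (!is.null(out_dir)) write_labeling(lab, out_dir)
  invisible(lab)
}

write_labeling <- function(lab, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (set in c("positive", "negative", "unsure")) {
    write_sites_vcf(filter(lab$labels, .data$label == set),
                    file.path(out_dir, paste0(set, ".vcf")))
  }
  readr::write_tsv(lab$labels, file.path(out_dir, "labels.tsv"),
                   progress = FALSE)
  readr::write_tsv(arrange(lab$calls, .data$cell_id, .data$chrom, .data$pos,
                           .data$ref, .data$alt),
                   file.path(out_dir, "calls.tsv"), progress = FALSE)
  cfg <- lab$config
  log <- list(config = unclass(cfg)[!vapply(unclass(cfg), is.null, logical(1))],
              bounds = lab$bounds, ledger = lab$ledger)
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Reload a written labeling from a run directory
#'
#' @param run_dir Directory written by [resa_run()].
#' @return A `resa_labeling` object.
#' @export
read_labeling <- function(run_dir) {
  labels <- readr::read_tsv(file.path(run_dir, "labels.tsv"),
                            show_col_types = FALSE, progress = FALSE)
  calls <- readr::read_tsv(file.path(run_dir, "calls.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  log <- jsonlite::read_json(file.path(run_dir, "run_log.json"),
                             simplifyVector = TRUE)
  cfg <- do.call(resa_config, log$config[setdiff(names(log$config), "n_cells")])
  cfg$n_cells <- log$config$n_cells
  structure(list(labels = labels, calls = calls,
                 bounds = list(L = log$bounds$L, U = log$bounds$U),
                 config = cfg, ledger = log$ledger),
            class = "resa_labeling")
}

#' Refine the unsure set with the joint classifier and write the final set
#'
#' File-level wrapper over [resa_jlr()]: fits the classifier on a labeling
#' (in memory or reloaded from a run directory), refines the unsure set, and
#' writes `final_positive.vcf`, `model.json` (coefficients, scaler, AUC and
#' configuration) and `predictions.tsv`.
#'
#' @param labeling A `resa_labeling` or a run directory path.
#' @param reference FASTA path or `DNAStringSet`.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @inheritParams resa_jlr
#' @return The `resa_jlr` object, invisibly when writing.
#' @export
resa_refine <- function(labeling, reference, signatures = NULL, out_dir = NULL,
                        threshold = 0.5, w_cutoff = 0.5, c_quality = 1,
                        c_sequence = 1, seed = NULL) {
  if (is.character(labeling)) labeling <- read_labeling(labeling)
  model <- resa_jlr(labeling, reference, signatures = signatures,
                    threshold = threshold, w_cutoff = w_cutoff,
                    c_quality = c_quality, c_sequence = c_sequence, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_sites_vcf(model$final_positive,
                    file.path(out_dir, "final_positive.vcf"))
    readr::write_tsv(model$predictions, file.path(out_dir, "predictions.tsv"),
                     progress = FALSE)
    coefs <- jlr_coefficients(model)
    jsonlite::write_json(
      list(test_auc = model$test_auc, threshold = model$threshold,
           w_cutoff = model$w_cutoff, seed = model$seed,
           c_quality = model$c_quality, c_sequence = model$c_sequence,
           n_train = model$n_train, n_test = model$n_test,
           scaler = model$submodels$scaler,
           coefficients = split(setNames(coefs$estimate, coefs$term),
                                coefs$submodel)),
      file.path(out_dir, "model.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
  }
  invisible(model)
}
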