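#' Configuration for the filtering-and-labeling engine
#'
#' Holds the thresholds driving quality filtering and cross-cell recurrence
#' bounding. The effective recurrence bounds for a cohort of `n_cells` cells
#' are `L = max(recurrence_floor, ceiling(recurrence_lower_frac * n_cells))`
#' and `U = floor(recurrence_upper_frac * n_cells)`: a candidate must be seen
#' in at least L cells (clonal signal) and at most U cells (above which it is
#' treated as a germline polymorphism or systematic artefact).
#'
#' @param n_cells Number of cells in the cohort (`NULL` to take it from the
#'   data at run time).
#' @param min_depth Minimum total read depth per call (default 3).
#' @param recurrence_floor Absolute lower recurrence bound X (default 3).
#' @param recurrence_lower_frac Fractional lower bound (default 0.10).
#' @param recurrence_upper_frac Fractional upper bound (default 0.80).
#' @param qd_min Minimum quality-by-depth; calls with QD below this fail
#'   quality (default 2.0).
#' @param fs_max Maximum Phred-scaled Fisher strand bias (default 30.0).
#' @param negative_max_recurrence Maximum recurrence for a key to count as
#'   showing "no cross-cell recurrence" (default 1, the strictest reading).
#' @param seed Integer seed used by downstream stochastic steps.
#' @return An object of class `resa_config` (a named list).
#' @export
resa_config <- function(n_cells = NULL, min_depth = 3L, recurrence_floor = 3L,
                        recurrence_lower_frac = 0.10,
                        recurrence_upper_frac = 0.80,
                        qd_min = 2.0, fs_max = 30.0,
                        negative_max_recurrence = 1L, seed = 17L) {
  if (recurrence_floor < 1) abort("recurrence_floor must be >= 1")
  if (!(recurrence_lower_frac > 0 && recurrence_lower_frac < recurrence_upper_frac &&
        recurrence_upper_frac <= 1)) {
    abort("need 0 < recurrence_lower_frac < recurrence_upper_frac <= 1")
  }
  cfg <- list(n_cells = n_cells, min_depth = min_depth,
              recurrence_floor = as.integer(recurrence_floor),
              recurrence_lower_frac = recurrence_lower_frac,
              recurrence_upper_frac = recurrence_upper_frac,
              qd_min = qd_min, fs_max = fs_max,
              negative_max_recurrence = as.integer(negative_max_recurrence),
              seed = as.integer(seed))
  class(cfg) <- "resa_config"
  if (!is.null(n_cells)) recurrence_bounds(cfg, n_cells) # validates L <= U
  cfg
}

#' Effective recurrence bounds for a cohort size
#'
#' @param cfg A [resa_config()].
#' @param n_cells Cohort size.
#' @return Named list with integers `L` and `U`.
#' @export
recurrence_bounds <- function(cfg, n_cells) {
  L <- max(cfg$recurrence_floor, ceiling(cfg$recurrence_lower_frac * n_cells))
  U <- floor(cfg$recurrence_upper_frac * n_cells)
  if (L > U) {
    abort(sprintf("recurrence bounds are empty for %d cells (L=%d > U=%d)",
                  n_cells, L, U))
  }
  list(L = as.integer(L), U = as.integer(U))
}

#' Annotation-based filtering of candidate calls
#'
#' Removes, in order, calls at non-exonic positions, at known RNA-editing
#' sites (matched by chromosome and position), and at germline-listed sites
#' (matched by full variant key). The first matching reason wins. The
#' surviving calls are the primary filtered candidates.
#'
#' @param calls Tibble of caller-G calls ([parse_cell_vcf()] schema).
#' @param exons A [GenomicRanges::GRanges] of exon intervals.
#' @param editing Editing site list (tibble with `chrom`, `pos`), or `NULL`.
#' @param germline A germline site list (tibble with `chrom`, `pos`, `ref`,
#'   `alt`) or a list of them (e.g. population plus matched normal); `NULL`
#'   or empty lists are allowed with a warning.
#' @return A list with `kept` (surviving calls), `removed` (one row per
#'   removed key: key columns plus `reason`) and `ledger` (named counts of
#'   removed keys per reason).
#' @export
annotation_filter <- function(calls, exons, editing = NULL, germline = NULL) {
  if (length(exons) == 0) abort("exon interval set is empty; nothing could survive")
  calls <- as_tibble(calls)
  keys <- arrange_keys(distinct(calls[, KEY_COLS]))
  if (is.null(editing) || nrow(editing) == 0) {
    if (!is.null(editing)) warn("editing site list is empty")
    editing <- tibble(chrom = character(), pos = integer())
  }
  if (is.null(germline)) germline <- list()
  if (is.data.frame(germline)) germline <- list(germline)
  germline <- purrr::keep(germline, ~ nrow(.x) > 0)
  if (length(germline) == 0) warn("no germline sites supplied; no germline removals")
  germ_ids <- unique(unlist(lapply(germline, key_id)))

  exonic <- keys_in_ranges(keys, exons)
  is_edit <- site_id(keys) %in% site_id(editing)
  is_germ <- key_id(keys) %in% germ_ids
  reason <- dplyr::case_when(
    !exonic ~ "non_exonic",
    is_edit ~ "editing",
    is_germ ~ "germline_list",
    TRUE ~ "none"
  )
  removed <- mutate(keys, reason = reason) |> filter(reason != "none")
  kept <- calls[key_id(calls) %in% key_id(keys[reason == "none", ]), ]
  ledger <- c(non_exonic = sum(reason == "non_exonic"),
              editing = sum(reason == "editing"),
              germline_list = sum(reason == "germline_list"))
  list(kept = kept, removed = removed, ledger = ledger)
}

#' Per-call quality predicate
#'
#' A call passes quality iff its depth is at least `min_depth`, its
#' quality-by-depth is at least `qd_min` (absent QD passes), its strand-bias
#' Phred score is at most `fs_max` (absent FS passes), and at least one read
#' supports the alternate allele.
#'
#' @param calls Tibble of calls.
#' @param cfg A [resa_config()].
#' @return Logical vector, one element per call.
#' @export
quality_pass <- function(calls, cfg = resa_config()) {
  with(calls,
       !is.na(dp) & dp >= cfg$min_depth &
       (is.na(qd) | qd >= cfg$qd_min) &
       (is.na(fs) | fs <= cfg$fs_max) &
       !is.na(ad_alt) & ad_alt >= 1)
}

#' Dual-caller consensus set assignment
#'
#' Per cell, a caller-G key called by both pipelines belongs to set A
#' (the dual-caller intersection); a key seen only by caller G belongs to
#' set B. Keys seen only by the secondary caller are ignored, since the
#' primary pipeline is the reference for downstream analysis.
#'
#' @param calls_g Caller-G calls (typically post [annotation_filter()]).
#' @param calls_s Caller-S calls (already PASS-restricted on ingest).
#' @return `calls_g` with an added `set` column (`"A"` or `"B"`).
#' @export
assign_sets <- function(calls_g, calls_s) {
  calls_g <- as_tibble(calls_g)
  calls_s <- as_tibble(calls_s)
  g_cells <- unique(calls_g$cell_id)
  missing_s <- setdiff(g_cells, unique(calls_s$cell_id))
  if (length(missing_s) > 0) {
    warn(sprintf("%d cell(s) have no secondary-caller calls; all their keys are set B",
                 length(missing_s)))
  }
  s_ids <- paste(calls_s$cell_id, key_id(calls_s))
  mutate(calls_g,
         set = if_else(paste(.data$cell_id, key_id(calls_g)) %in% s_ids, "A", "B"))
}

#' Cross-cell recurrence counts
#'
#' Counts, for every variant key, the number of distinct cells in which it was
#' called by the primary pipeline (after annotation filtering, before quality
#' filtering — recurrence is a pseudo-bulk detection count).
#'
#' @param calls Tibble of post-annotation caller-G calls across all cells.
#' @return Tibble with key columns and `recurrence`.
#' @export
recurrence_counts <- function(calls) {
  as_tibble(calls) |>
    group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    summarise(recurrence = n_distinct(.data$cell_id), .groups = "drop") |>
    arrange_keys()
}

#' Partition candidate keys into positive / negative / unsure / removed
#'
#' Applies the cohort-level labeling rules. With recurrence bounds L and U
#' derived from the configuration:
#' * `removed` (reason `over_recurrent`): recurrence > U — putative germline
#'   polymorphisms or systematic artefacts;
#' * `positive`: at least one quality-passing set-A call and L <= recurrence
#'   <= U — the high-confidence somatic set;
#' * `negative`: only set-B calls, none quality-passing, and no cross-cell
#'   recurrence (recurrence <= `negative_max_recurrence`, default 1) — the
#'   high-confidence artefact set;
#' * `unsure`: everything else, deferred to the classifier.
#'
#' @param calls Caller-G calls with `set` ([assign_sets()]) for the whole
#'   cohort (post annotation filtering).
#' @param cfg A [resa_config()]; `n_cells`, if set, must match the data.
#' @param removed Optional removed-key tibble from [annotation_filter()],
#'   appended to the output with label `"removed"`.
#' @return Object of class `resa_labeling`: list with `labels` (one row per
#'   key: key columns, `label`, `reason`, `recurrence`, `n_cells_a`,
#'   `n_pass_a`), `calls` (the input calls with `quality_pass` and
#'   `recurrence`), `bounds`, `config` and `ledger`.
#' @export
label_cohort <- function(calls, cfg = resa_config(), removed = NULL) {
  calls <- as_tibble(calls)
  n_obs <- n_distinct(calls$cell_id)
  if (!is.null(cfg$n_cells) && cfg$n_cells != n_obs) {
    abort(sprintf("config says %d cells but %d observed", cfg$n_cells, n_obs))
  }
  n_cells <- cfg$n_cells %||% n_obs
  b <- recurrence_bounds(cfg, n_cells)
  rec <- recurrence_counts(calls)
  calls <- calls |>
    mutate(quality_pass = quality_pass(calls, cfg)) |>
    left_join(rec, by = KEY_COLS)

  labels <- calls |>
    group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    summarise(
      recurrence = .data$recurrence[1],
      n_cells_a = n_distinct(.data$cell_id[.data$set == "A"]),
      n_pass_a = sum(.data$set == "A" & .data$quality_pass),
      any_pass = any(.data$quality_pass),
      b_only = all(.data$set == "B"),
      .groups = "drop"
    ) |>
    mutate(
      label = dplyr::case_when(
        .data$recurrence > b$U ~ "removed",
        .data$n_pass_a > 0 & .data$recurrence >= b$L ~ "positive",
        .data$b_only & !.data$any_pass &
          .data$recurrence <= cfg$negative_max_recurrence ~ "negative",
        TRUE ~ "unsure"
      ),
      reason = if_else(.data$label == "removed", "over_recurrent", "none")
    ) |>
    select(dplyr::all_of(KEY_COLS), "label", "reason", "recurrence",
           "n_cells_a", "n_pass_a") |>
    arrange_keys()

  if (!is.null(removed) && nrow(removed) > 0) {
    labels <- bind_rows(labels, removed |>
      mutate(label = "removed", recurrence = NA_integer_,
             n_cells_a = NA_integer_, n_pass_a = NA_integer_)) |>
      arrange_keys()
  }
  ledger <- table(factor(labels$label,
                         levels = c("positive", "negative", "unsure", "removed")))
  structure(list(labels = labels, calls = calls, bounds = b, config = cfg,
                 ledger = as.list(ledger)),
            class = "resa_labeling")
}

#' Run the full filtering-and-labeling engine on in-memory calls
#'
#' Convenience wrapper chaining [annotation_filter()], [assign_sets()] and
#' [label_cohort()].
#'
#' @param calls_g,calls_s Cohort-wide caller-G and caller-S call tibbles.
#' @param exons Exon [GenomicRanges::GRanges].
#' @param editing,germline Site lists as in [annotation_filter()].
#' @param cfg A [resa_config()].
#' @return A `resa_labeling` object (see [label_cohort()]).
#' @export
resa_label <- function(calls_g, calls_s, exons, editing = NULL, germline = NULL,
                       cfg = resa_config()) {
  ann <- annotation_filter(calls_g, exons, editing, germline)
  withs <- assign_sets(ann$kept, calls_s)
  lab <- label_cohort(withs, cfg, removed = ann$removed)
  lab$ledger <- c(lab$ledger, as.list(ann$ledger))
  lab
}

#' @export
print.resa_labeling <- function(x, ...) {
  cat("<resa_labeling> ", n_distinct(x$calls$cell_id), " cells, ",
      nrow(x$labels), " candidate keys\n", sep = "")
  cat("  recurrence bounds: [", x$bounds$L, ", ", x$bounds$U, "]\n", sep = "")
  counts <- table(x$labels$label)
  cat(" ", paste(names(counts), counts, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' @describeIn label_cohort Tidy the per-key label table.
#' @param x A `resa_labeling` object.
#' @param ... Unused.
#' @export
tidy.resa_labeling <- function(x, ...) x$labels

#' @describeIn label_cohort One-row cohort summary (set sizes and bounds).
#' @export
glance.resa_labeling <- function(x, ...) {
  tibble(n_cells = n_distinct(x$calls$cell_id),
         n_keys = nrow(x$labels),
         n_positive = sum(x$labels$label == "positive"),
         n_negative = sum(x$labels$label == "negative"),
         n_unsure = sum(x$labels$label == "unsure"),
         n_removed = sum(x$labels$label == "removed"),
         rec_lower = x$bounds$L, rec_upper = x$bounds$U)
}

#' @describeIn label_cohort Bar chart of the label partition.
#' @param object A `resa_labeling` object.
#' @export
autoplot.resa_labeling <- function(object, ...) {
  df <- count(object$labels, .data$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$n, fill = .data$label)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "candidate variant keys",
                  title = "Cohort label partition") +
    ggplot2::theme_minimal()
}
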