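#' Stratified 3:1 train/test split
#'
#' Splits labeled rows into training and held-out test sets at a 3:1 ratio,
#' stratified by class so both classes appear on each side, deterministic
#' given the seed. Each class keeps at least one row in the test set.
#'
#' @param y 0/1 label vector.
#' @param seed Integer seed.
#' @param train_frac Training fraction (default 0.75).
#' @return List with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(y, seed, train_frac = 0.75) {
  if (length(y) < 8) abort("need at least 8 labeled rows to split")
  if (any(table(factor(y, levels = 0:1)) < 2)) {
    abort("each class needs at least 2 rows to stratify the split")
  }
  train <- integer(0)
  set.seed(seed)
  for (cls in c(0, 1)) {
    idx <- which(y == cls)
    n_tr <- max(1L, min(length(idx) - 1L, floor(length(idx) * train_frac + 0.5)))
    train <- c(train, sort(sample(idx, n_tr)))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}

#' Random oversampling of the minority class
#'
#' Resamples minority-class rows with replacement until the class counts are
#' equal; majority rows are untouched. Deterministic given the seed.
#'
#' @param y 0/1 label vector for the training rows.
#' @param seed Integer seed.
#' @return Integer row indices (into `y`) of the balanced training set, with
#'   original rows first.
#' @export
oversample_minority <- function(y, seed) {
  n0 <- sum(y == 0); n1 <- sum(y == 1)
  if (n0 == 0 || n1 == 0) abort("both classes must be present to oversample")
  if (n0 == n1) return(seq_along(y))
  minority <- if (n0 < n1) which(y == 0) else which(y == 1)
  set.seed(seed)
  extra <- sample(minority, abs(n0 - n1), replace = TRUE)
  c(seq_along(y), extra)
}

fit_penalized_logistic <- function(x, y, alpha, C) {
  lambda <- 1 / (nrow(x) * C)
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                        lambda = lambda, standardize = FALSE, thresh = 1e-9)
  if (anyNA(as.numeric(stats::coef(fit)))) {
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                          lambda = lambda, standardize = FALSE, thresh = 1e-9,
                          maxit = 1e6)
    if (anyNA(as.numeric(stats::coef(fit)))) {
      abort("penalized logistic fit failed to converge")
    }
  }
  fit
}

#' Fit the joint logistic-regression classifier
#'
#' Trains two penalized logistic submodels on the same rows: an L1 (lasso)
#' model on z-score-standardized quality features, and an L2 (ridge) model on
#' one-hot sequence features (plus optional signature components). The
#' penalty strength is parameterized as in liblinear-style solvers
#' (`lambda = 1 / (n * C)`).
#'
#' @param x_quality,x_sequence Training matrices (same rows).
#' @param y 0/1 labels.
#' @param c_quality,c_sequence Inverse regularization strengths (default 1).
#' @return List with the two `glmnet` fits and the quality-feature scaler
#'   (`center`, `scale` from the training data).
#' @keywords internal
fit_submodels <- function(x_quality, x_sequence, y,
                          c_quality = 1, c_sequence = 1) {
  center <- colMeans(x_quality)
  scale <- apply(x_quality, 2, stats::sd)
  scale[scale == 0 | is.na(scale)] <- 1
  xq <- sweep(sweep(x_quality, 2, center), 2, scale, "/")
  list(
    quality = fit_penalized_logistic(xq, y, alpha = 1, C = c_quality),
    sequence = fit_penalized_logistic(x_sequence, y, alpha = 0, C = c_sequence),
    scaler = list(center = center, scale = scale)
  )
}

predict_submodels <- function(sub, x_quality, x_sequence) {
  xq <- sweep(sweep(x_quality, 2, sub$scaler$center), 2, sub$scaler$scale, "/")
  tibble(
    p_pos = as.numeric(predict(sub$quality, xq, type = "response")),
    p_seq = as.numeric(predict(sub$sequence, x_sequence, type = "response"))
  )
}

#' The joint probability combination rule
#'
#' Combines the sequence- and quality-submodel positive-class probabilities
#' into \eqn{P(pos) = \frac{1}{2}\sum_{P \in (P_{seq}, P_{pos})} wP} where
#' \eqn{w = 1} if \eqn{P \ge w_{cutoff}} (default 0.5) and 0 otherwise. A
#' submodel below the cutoff therefore contributes nothing; the joint
#' probability is 0 when both are below it, and the default decision calls a
#' variant positive when the result is at least 0.5.
#'
#' @param p_seq,p_pos Probabilities in \[0, 1\] (vectorized).
#' @param w_cutoff Per-submodel weight cutoff (default 0.5).
#' @return Numeric vector of joint probabilities.
#' @export
#' @examples
#' joint_probability(0.8, 0.6)  # 0.7
#' joint_probability(0.4, 0.3)  # 0 -- both weights are zero
#' joint_probability(1.0, 0.4)  # 0.5 -- a lone certain submodel just clears 0.5
joint_probability <- function(p_seq, p_pos, w_cutoff = 0.5) {
  if (any(is.na(p_seq) | is.na(p_pos)) ||
      any(p_seq < 0 | p_seq > 1 | p_pos < 0 | p_pos > 1)) {
    abort("probabilities must lie in [0, 1]")
  }
  0.5 * ((p_seq >= w_cutoff) * p_seq + (p_pos >= w_cutoff) * p_pos)
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed from the Wilcoxon rank statistic, with
#' ties averaged.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @return AUC in \[0, 1\]; `NA` with a warning for a single-class input.
#' @export
auc_score <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    warn("AUC undefined for a single-class label set")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit and apply the joint classifier to refine the unsure set
#'
#' End-to-end modeling step: builds design matrices from a labeling, splits
#' the labeled keys 3:1 (stratified), balances the training set by random
#' oversampling, fits the L1 quality and L2 sequence submodels, evaluates the
#' joint classifier's AUC on the held-out test keys, scores the unsure set
#' with the joint rule, and returns the final positive set — the core
#' positives plus the predicted-positive unsure keys. Refinement only ever
#' adds variants.
#'
#' @param labeling A `resa_labeling`.
#' @param reference FASTA path or `DNAStringSet`.
#' @param signatures Optional signature matrix or TSV path.
#' @param threshold Joint-probability decision threshold (default 0.5).
#' @param w_cutoff Per-submodel weight cutoff inside the combination rule
#'   (default 0.5).
#' @param c_quality,c_sequence Inverse regularization strengths (default 1).
#' @param aggregate Per-key quality aggregation, `"mean"` or `"max_qual"`.
#' @param seed Seed for the split and oversampling (defaults to the
#'   labeling's config seed).
#' @return Object of class `resa_jlr` with elements `submodels`, `test_auc`,
#'   `predictions` (per unsure key: `p_pos`, `p_seq`, `p_joint`, `call`),
#'   `final_positive` (key tibble with `provenance` = `"core"`/`"refined"`),
#'   `test` (held-out scores and labels), `threshold`, `w_cutoff`, `seed` and
#'   `dropped` (keys excluded for undefined sequence context).
#' @export
resa_jlr <- function(labeling, reference, signatures = NULL, threshold = 0.5,
                     w_cutoff = 0.5, c_quality = 1, c_sequence = 1,
                     aggregate = c("mean", "max_qual"), seed = NULL) {
  if (!(threshold > 0 && threshold < 1)) abort("threshold must be in (0, 1)")
  seed <- as.integer(seed %||% labeling$config$seed)
  dm <- build_design_matrices(labeling, reference, signatures,
                              aggregate = match.arg(aggregate))
  y <- dm$labeled$y
  sp <- split_train_test(y, seed = seed)
  bal <- oversample_minority(y[sp$train], seed = seed + 1L)
  tr <- sp$train[bal]
  sub <- fit_submodels(dm$labeled$quality[tr, , drop = FALSE],
                       dm$labeled$sequence[tr, , drop = FALSE],
                       y[tr], c_quality, c_sequence)

  p_test <- predict_submodels(sub, dm$labeled$quality[sp$test, , drop = FALSE],
                              dm$labeled$sequence[sp$test, , drop = FALSE])
  p_test$p_joint <- joint_probability(p_test$p_seq, p_test$p_pos, w_cutoff)
  test_auc <- auc_score(p_test$p_joint, y[sp$test])

  preds <- dm$unsure$keys
  if (nrow(preds) > 0) {
    pu <- predict_submodels(sub, dm$unsure$quality, dm$unsure$sequence)
    preds <- dplyr::bind_cols(preds, pu) |>
      mutate(p_joint = joint_probability(.data$p_seq, .data$p_pos, w_cutoff),
             call = .data$p_joint >= threshold)
  } else {
    preds <- mutate(preds, p_pos = numeric(0), p_seq = numeric(0),
                    p_joint = numeric(0), call = logical(0))
  }

  core <- filter(labeling$labels, .data$label == "positive")[, KEY_COLS]
  refined <- filter(preds, .data$call)[, KEY_COLS]
  final <- bind_rows(mutate(core, provenance = "core"),
                     mutate(refined, provenance = "refined")) |>
    arrange_keys()

  structure(list(submodels = sub, test_auc = test_auc, predictions = preds,
                 final_positive = final,
                 test = tibble(y = y[sp$test], p_joint = p_test$p_joint,
                               p_pos = p_test$p_pos, p_seq = p_test$p_seq),
                 n_train = length(sp$train), n_test = length(sp$test),
                 threshold = threshold, w_cutoff = w_cutoff, seed = seed,
                 c_quality = c_quality, c_sequence = c_sequence,
                 dropped = bind_rows(dm$labeled$dropped, dm$unsure$dropped)),
            class = "resa_jlr")
}

jlr_coefficients <- function(model) {
  cq <- as.matrix(stats::coef(model$submodels$quality))
  cs <- as.matrix(stats::coef(model$submodels$sequence))
  bind_rows(
    tibble(submodel = "quality", term = rownames(cq), estimate = cq[, 1]),
    tibble(submodel = "sequence", term = rownames(cs), estimate = cs[, 1])
  )
}

#' @export
print.resa_jlr <- function(x, ...) {
  cat("<resa_jlr> held-out AUC:", format(x$test_auc, digits = 3),
      " (", x$n_train, "train /", x$n_test, "test keys )\n")
  cat("  final positive set:", nrow(x$final_positive), "keys (",
      sum(x$final_positive$provenance == "refined"), "refined )\n")
  invisible(x)
}

#' @describeIn resa_jlr Coefficients of both submodels, one row per term.
#' @param x A `resa_jlr` object.
#' @param ... Unused.
#' @export
tidy.resa_jlr <- function(x, ...) jlr_coefficients(x)

#' @describeIn resa_jlr One-row model summary.
#' @export
glance.resa_jlr <- function(x, ...) {
  tibble(test_auc = x$test_auc, n_train = x$n_train, n_test = x$n_test,
         n_unsure = nrow(x$predictions),
         n_core = sum(x$final_positive$provenance == "core"),
         n_refined = sum(x$final_positive$provenance == "refined"),
         threshold = x$threshold, w_cutoff = x$w_cutoff)
}

#' @describeIn resa_jlr ROC curve of the joint classifier on the held-out
#'   test keys.
#' @param object A `resa_jlr` object.
#' @export
autoplot.resa_jlr <- function(object, ...) {
  df <- object$test |> arrange(dplyr::desc(.data$p_joint)) |>
    mutate(tpr = cumsum(.data$y == 1) / sum(.data$y == 1),
           fpr = cumsum(.data$y == 0) / sum(.data$y == 0))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("Held-out ROC (AUC = %.3f)", object$test_auc)) +
    ggplot2::theme_minimal()
}
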