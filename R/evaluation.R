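# Multi-class evaluation arithmetic.
#
# Each class in turn is treated as positive and the remaining classes as
# negative (one-vs-rest), giving per-class counts TP, FP, TN, FN with
# TP + FP + TN + FN = N. Per class:
#
#   accuracy    = (TP + TN) / (TP + FP + TN + FN)
#   precision   = TP / (TP + FP)
#   specificity = TN / (TN + FP)
#   sensitivity = TP / (TP + FN)
#   f1          = 2 * precision * sensitivity / (precision + sensitivity)
#
# and the summary numbers are unweighted macro averages (arithmetic mean
# over classes) of each metric. A zero denominator yields NaN with a
# warning, never a silent 0, and NaN propagates into macro means.

metric_cols <- c("accuracy", "sensitivity", "precision", "specificity",
                 "f1")

#' One-vs-rest confusion counts
#'
#' @param y_true,y_pred Integer label vectors in `1:n_classes`.
#' @param n_classes Number of classes.
#' @param class_names Optional class names for the output.
#' @return A tibble with one row per class: `class`, `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(y_true, y_pred, n_classes,
                             class_names = NULL) {
  if (length(y_true) == 0L) abort("empty input")
  if (length(y_true) != length(y_pred)) {
    abort("`y_true` and `y_pred` must have equal length")
  }
  n_classes <- assert_scalar_int(n_classes, "n_classes", min = 2L)
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (any(c(y_true, y_pred) < 1L) || any(c(y_true, y_pred) > n_classes)) {
    abort("labels out of range 1:n_classes")
  }
  class_names <- class_names %||% paste0("class", seq_len(n_classes))
  n <- length(y_true)
  out <- purrr::map_dfr(seq_len(n_classes), function(k) {
    tp <- sum(y_true == k & y_pred == k)
    fp <- sum(y_true != k & y_pred == k)
    fn <- sum(y_true == k & y_pred != k)
    tibble(class = class_names[k], tp = tp, fp = fp,
           tn = n - tp - fp - fn, fn = fn)
  })
  out
}

safe_div <- function(num, den, what) {
  bad <- !is.na(den) & den == 0
  if (any(bad)) {
    warn(sprintf("zero denominator in %s for %d class(es); reporting NaN",
                 what, sum(bad)))
  }
  out <- num / den                   # NaN inputs propagate as NaN
  out[bad] <- NaN
  out
}

#' Per-class metrics from confusion counts
#'
#' Applies the five one-vs-rest formulas (accuracy, sensitivity, precision,
#' specificity, F1) to each class row. Metrics are proportions in
#' \[0, 1\]; multiply by 100 for the percentage scale used in printed
#' tables.
#'
#' @param counts A tibble from [confusion_counts()].
#' @return A tibble with `class` plus the five metric columns.
#' @export
per_class_metrics <- function(counts) {
  stopifnot(all(c("class", "tp", "fp", "tn", "fn") %in% names(counts)))
  with(counts, {
    precision <- safe_div(tp, tp + fp, "precision")
    sensitivity <- safe_div(tp, tp + fn, "sensitivity")
    tibble(
      class = class,
      accuracy = safe_div(tp + tn, tp + fp + tn + fn, "accuracy"),
      sensitivity = sensitivity,
      precision = precision,
      specificity = safe_div(tn, tn + fp, "specificity"),
      f1 = safe_div(2 * precision * sensitivity, precision + sensitivity,
                    "f1"))
  })
}

#' Macro (unweighted) averages of per-class metrics
#'
#' The arithmetic mean over classes of each metric column, deliberately
#' unweighted even under class imbalance. NaN per-class entries propagate
#' with a warning.
#'
#' @param metrics A per-class metric tibble (from [per_class_metrics()] or
#'   [aggregate_runs()]); any numeric columns are averaged.
#' @return A one-row tibble of macro averages.
#' @export
macro_average <- function(metrics) {
  if (nrow(metrics) < 1L) abort("need at least one class")
  num <- metrics[vapply(metrics, is.numeric, logical(1))]
  if ("run" %in% names(num)) num$run <- NULL
  out <- dplyr::summarise(num, dplyr::across(dplyr::everything(),
                                             ~ mean(.x)))
  if (anyNA(out)) warn("NaN per-class metric propagated into macro average")
  as_tibble(out)
}

#' Full metrics report for a set of predictions
#'
#' Convenience wrapper: confusion counts, per-class metrics, and macro
#' averages in one long tibble (classes plus a `"macro"` row).
#'
#' @inheritParams confusion_counts
#' @return A tibble with `class` (including `"macro"`) and the five metric
#'   columns.
#' @export
metrics_report <- function(y_true, y_pred, n_classes,
                           class_names = NULL) {
  pc <- per_class_metrics(confusion_counts(y_true, y_pred, n_classes,
                                           class_names))
  dplyr::bind_rows(pc, dplyr::bind_cols(tibble(class = "macro"),
                                        macro_average(pc)))
}

#' Average per-class metrics over repeated runs
#'
#' Element-wise mean over runs of every per-class metric (the cross-run
#' summary used when classifier training is repeated with re-randomized
#' hidden layers). Macro averages should then be recomputed from the
#' aggregated per-class values with [macro_average()]. Rounding for display
#' is left to printing.
#'
#' @param reports A list of per-class metric tibbles, or one long tibble
#'   with a `run` column.
#' @return A per-class tibble of run-averaged metrics.
#' @export
aggregate_runs <- function(reports) {
  long <- if (is.data.frame(reports)) {
    reports
  } else {
    tabs <- purrr::imap(reports, ~ dplyr::mutate(.x, run = .y))
    classes <- purrr::map(tabs, ~ .x$class)
    if (!all(purrr::map_lgl(classes, identical, classes[[1]]))) {
      abort("all reports must share the same class table")
    }
    dplyr::bind_rows(tabs)
  }
  long |>
    dplyr::filter(.data$class != "macro") |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric) &
                                     !dplyr::any_of("run"),
                                   ~ mean(.x)),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$class, unique(long$class)))
}

#' One-vs-rest ROC AUC
#'
#' For each class, the area under the ROC curve obtained by sweeping a
#' threshold over that class's score column, computed by trapezoidal
#' integration. Tied scores contribute diagonal ROC segments, so the result
#' equals the pairwise concordance probability with ties counted 1/2.
#'
#' @param scores N x m matrix of continuous class scores (e.g. raw
#'   randomized-network outputs).
#' @param y_true Integer labels in `1:m`.
#' @param class_names Optional class names.
#' @return A tibble with `class` and `auc`; a class absent from `y_true`
#'   (or covering all of it) yields NaN with a warning.
#' @export
roc_auc_ovr <- function(scores, y_true, class_names = NULL) {
  scores <- as.matrix(scores)
  if (any(!is.finite(scores))) abort("scores must be finite")
  m <- ncol(scores)
  if (m < 2L) abort("need at least 2 score columns")
  if (nrow(scores) != length(y_true)) {
    abort("nrow(scores) must equal length(y_true)")
  }
  y_true <- as.integer(y_true)
  class_names <- class_names %||% paste0("class", seq_len(m))
  auc <- vapply(seq_len(m), function(k) {
    pos <- y_true == k
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0L || n0 == 0L) {
      warn(sprintf("class %s absent from one side; AUC is NaN",
                   class_names[k]))
      return(NaN)
    }
    roc_trapezoid(scores[, k], pos)
  }, numeric(1))
  tibble(class = class_names, auc = auc)
}

# Trapezoidal area under the ROC built from the unique score thresholds in
# decreasing order; ties advance TPR and FPR simultaneously, producing the
# midpoint (concordance) convention.
roc_trapezoid <- function(s, pos) {
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; pos <- pos[ord]
  n1 <- sum(pos); n0 <- sum(!pos)
  grp_end <- c(diff(s) != 0, TRUE)       # last index of each tie group
  tpr <- c(0, cumsum(pos)[grp_end] / n1)
  fpr <- c(0, cumsum(!pos)[grp_end] / n0)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

#' ROC curve points, one curve per class
#'
#' @inheritParams roc_auc_ovr
#' @return A tibble with `class`, `fpr`, `tpr` suitable for plotting or CSV
#'   export.
#' @export
roc_points_ovr <- function(scores, y_true, class_names = NULL) {
  scores <- as.matrix(scores)
  m <- ncol(scores)
  class_names <- class_names %||% paste0("class", seq_len(m))
  y_true <- as.integer(y_true)
  purrr::map_dfr(seq_len(m), function(k) {
    pos <- y_true == k
    if (sum(pos) == 0L || sum(!pos) == 0L) return(tibble())
    s <- scores[, k]
    ord <- order(s, decreasing = TRUE)
    s <- s[ord]; p <- pos[ord]
    grp_end <- c(diff(s) != 0, TRUE)
    tibble(class = class_names[k],
           fpr = c(0, cumsum(!p)[grp_end] / sum(!pos)),
           tpr = c(0, cumsum(p)[grp_end] / sum(pos)))
  })
}
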