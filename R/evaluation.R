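## Unknown-aware one-vs-rest evaluation.  Per class: TP/FP/TN/FN counts,
## the five derived metrics (sensitivity, specificity, precision,
## accuracy, MCC), the fraction of class members predicted Unknown, and a
## size-weighted overall average across classes.

#' One-vs-rest confusion counts for a class
#'
#' A protein is positive for class *c* when *c* is among its true tags
#' (multi-location truths such as CW-TM are positive for both classes)
#' and predicted positive when *c* is among its predicted tags. Under the
#' default policy (`unknown = "negative"`) an `Unknown` prediction counts
#' as a negative call for every class -- a true-*c* protein predicted
#' `Unknown` is a false negative for *c* and a true negative for the
#' others. With `unknown = "exclude"`, proteins predicted `Unknown` are
#' dropped before counting.
#'
#' @param table A data frame with `true_tags` and `predicted_tags`
#'   columns (`";"`-joined tag strings, as produced by the engine and the
#'   prediction I/O).
#' @param class One of the five localization classes.
#' @param unknown `"negative"` (default) or `"exclude"`.
#' @return Named integer vector `c(TP, FP, TN, FN)`; the four counts sum
#'   to the number of evaluated proteins.
#' @export
confusion_counts <- function(table, class, unknown = c("negative",
                                                       "exclude")) {
  unknown <- match.arg(unknown)
  stopifnot(class %in% SCL_CLASSES)
  sets <- checked_tag_sets(table)
  confusion_from_sets(sets$truth, sets$pred, class, unknown)
}

## Split and validate the two tag columns once (vectorized; shared by
## confusion_counts and evaluate_predictions so large tables are not
## re-parsed per class).
checked_tag_sets <- function(table) {
  truth <- split_tags(table$true_tags)
  pred <- split_tags(table$predicted_tags)
  if (any(lengths(truth) == 0L)) {
    input_error("every row must carry true_tags for evaluation")
  }
  check_tags <- function(sets, col) {
    bad <- setdiff(unique(unlist(sets, use.names = FALSE)), TAG_VOCAB)
    if (length(bad)) {
      row <- which(vapply(sets, function(s) any(s %in% bad),
                          logical(1L)))[1L]
      input_error(col, ", row ", row, ": unknown tag '", bad[1L], "'")
    }
  }
  check_tags(truth, "true_tags")
  check_tags(pred, "predicted_tags")
  list(truth = truth, pred = pred,
       is_unknown = vapply(pred, function(p) "Unknown" %in% p,
                           logical(1L)))
}

confusion_from_sets <- function(truth, pred, class, unknown) {
  is_unknown <- vapply(pred, function(p) "Unknown" %in% p, logical(1L))
  if (unknown == "exclude") {
    truth <- truth[!is_unknown]
    pred <- pred[!is_unknown]
  }
  t_pos <- vapply(truth, function(s) class %in% s, logical(1L))
  p_pos <- vapply(pred, function(s) class %in% s, logical(1L))
  c(TP = sum(t_pos & p_pos), FP = sum(!t_pos & p_pos),
    TN = sum(!t_pos & !p_pos), FN = sum(t_pos & !p_pos))
}

#' The five class metrics from confusion counts
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), precision TP/(TP+FP),
#' accuracy (TP+TN)/(TP+TN+FP+FN) and the Matthews correlation
#' coefficient (TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN)).
#' A zero denominator yields `NA` (undefined), never 0.
#'
#' @param counts Named vector with `TP`, `FP`, `TN`, `FN`.
#' @return Named numeric vector `sensitivity`, `specificity`,
#'   `precision`, `accuracy`, `mcc`.
#' @export
class_metrics <- function(counts) {
  tp <- as.numeric(counts[["TP"]]); fp <- as.numeric(counts[["FP"]])
  tn <- as.numeric(counts[["TN"]]); fn <- as.numeric(counts[["FN"]])
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  ## single sqrt of the product: exact for the degenerate perfect /
  ## reversed tables where the radicand is a perfect square
  mcc_den <- sqrt((tp + fn) * (tp + fp) * (tn + fp) * (tn + fn))
  c(sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    precision = ratio(tp, tp + fp),
    accuracy = ratio(tp + tn, tp + tn + fp + fn),
    mcc = if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den)
}

#' Size-weighted overall metrics
#'
#' The overall value of each metric is the class-size-weighted arithmetic
#' mean across classes; classes where a metric is undefined are excluded
#' from that metric's average with the remaining weights renormalized.
#'
#' @param per_class Data frame with one row per class and the metric
#'   columns.
#' @param sizes Numeric vector of class sizes (number of true members),
#'   aligned with `per_class` rows.
#' @return Named numeric vector of overall metrics.
#' @export
overall_metrics <- function(per_class, sizes) {
  stopifnot(nrow(per_class) == length(sizes))
  if (all(sizes == 0)) input_error("all class sizes are zero")
  cols <- c("sensitivity", "specificity", "precision", "accuracy", "mcc",
            "unknown_rate")
  cols <- intersect(cols, names(per_class))
  out <- vapply(cols, function(col) {
    v <- per_class[[col]]
    ok <- !is.na(v) & sizes > 0
    if (!any(ok)) return(NA_real_)
    sum(v[ok] * sizes[ok]) / sum(sizes[ok])
  }, numeric(1L))
  out
}

#' Evaluate a labeled prediction table
#'
#' Computes one-vs-rest confusion counts and the five metrics for every
#' localization class, the per-class `unknown_rate` (fraction of the
#' class's true members predicted `Unknown`, reported separately from the
#' confusion-based metrics), and the size-weighted overall row.
#'
#' @inheritParams confusion_counts
#' @param classes Classes to evaluate; defaults to the five localization
#'   classes that occur among the true tags.
#' @return A data frame of class `scl_metrics`: one row per class plus an
#'   `overall` row, columns `class`, `n`, `TP`, `FP`, `TN`, `FN`,
#'   `sensitivity`, `specificity`, `precision`, `accuracy`, `mcc`,
#'   `unknown_rate`.
#' @export
evaluate_predictions <- function(table, classes = NULL,
                                 unknown = c("negative", "exclude")) {
  unknown <- match.arg(unknown)
  sets <- checked_tag_sets(table)
  truth <- sets$truth
  if (is.null(classes)) {
    classes <- SCL_CLASSES[SCL_CLASSES %in% unlist(truth)]
  }
  if (!length(classes)) input_error("no evaluable classes in true_tags")
  is_unknown <- sets$is_unknown
  rows <- lapply(classes, function(cl) {
    cc <- confusion_from_sets(sets$truth, sets$pred, cl, unknown)
    m <- class_metrics(cc)
    members <- vapply(truth, function(s) cl %in% s, logical(1L))
    data.frame(class = cl, n = sum(members),
               TP = cc[["TP"]], FP = cc[["FP"]], TN = cc[["TN"]],
               FN = cc[["FN"]],
               sensitivity = m[["sensitivity"]],
               specificity = m[["specificity"]],
               precision = m[["precision"]], accuracy = m[["accuracy"]],
               mcc = m[["mcc"]],
               unknown_rate = if (sum(members) == 0) NA_real_ else
                 mean(is_unknown[members]),
               stringsAsFactors = FALSE)
  })
  per_class <- do.call(rbind, rows)
  ov <- overall_metrics(per_class, per_class$n)
  overall_row <- data.frame(class = "overall", n = sum(per_class$n),
                            TP = NA_integer_, FP = NA_integer_,
                            TN = NA_integer_, FN = NA_integer_,
                            sensitivity = ov[["sensitivity"]],
                            specificity = ov[["specificity"]],
                            precision = ov[["precision"]],
                            accuracy = ov[["accuracy"]],
                            mcc = ov[["mcc"]],
                            unknown_rate = ov[["unknown_rate"]],
                            stringsAsFactors = FALSE)
  out <- rbind(per_class, overall_row)
  rownames(out) <- NULL
  class(out) <- c("scl_metrics", "data.frame")
  out
}
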