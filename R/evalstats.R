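# Evaluation harness: accuracy, weighted F1, Brier score, per-split
# aggregation with max-mean reporting, one-sided paired t-tests, and
# single-class pathology detection.

#' Brier score
#'
#' Mean squared difference between predicted class-1 probabilities and the
#' binary labels; 0 is perfect, lower is better.
#'
#' @param p Probabilities in `[0, 1]`; `y` binary labels of equal length.
#' @param y Binary labels.
#' @return The Brier score in `[0, 1]`.
#' @export
brier_score <- function(p, y) {
  if (length(p) != length(y)) stop("length mismatch")
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  mean((p - y)^2)
}

#' Support-weighted F1 score
#'
#' Per-class F1 combined as `sum_c (support_c / N) * F1_c`; a class with no
#' predicted and no true positives contributes F1 = 0.
#'
#' @param y_true,y_pred Binary label vectors.
#' @return Weighted F1 in `[0, 1]` (1 for perfect prediction).
#' @export
weighted_f1 <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  f1_class <- function(cls) {
    tp <- sum(y_true == cls & y_pred == cls)
    fp <- sum(y_true != cls & y_pred == cls)
    fn <- sum(y_true == cls & y_pred != cls)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  classes <- sort(unique(y_true))
  sum(vapply(classes, function(cls) {
    mean(y_true == cls) * f1_class(cls)
  }, numeric(1)))
}

#' Classification accuracy
#' @param y_true,y_pred Binary label vectors.
#' @return Fraction of matching labels.
#' @export
accuracy_score <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  mean(y_true == y_pred)
}

#' All predictions in one class?
#'
#' Flags the degenerate regime where a classifier collapses to a single
#' label on a split.
#'
#' @param y_pred Predicted labels for one split.
#' @return `TRUE` iff every prediction shares one label.
#' @export
detect_single_class <- function(y_pred) {
  length(unique(y_pred)) == 1L
}

#' One split's metric record
#'
#' @param classifier Classifier identifier.
#' @param split Split identifier.
#' @param y_true True labels; `p` predicted class-1 probabilities.
#' @param p Predicted class-1 probabilities.
#' @return One-row data.frame with accuracy, weighted F1, Brier score and
#'   the single-class flag.
#' @export
metric_record <- function(classifier, split, y_true, p) {
  y_pred <- classify(p)
  data.frame(classifier = classifier, split = split,
             accuracy = accuracy_score(y_true, y_pred),
             weighted_f1 = weighted_f1(y_true, y_pred),
             brier = brier_score(p, y_true),
             single_class = detect_single_class(y_pred))
}

#' Aggregate metric records over splits
#'
#' Per classifier: mean and standard error (`sd / sqrt(n)`, 0 for a single
#' record) of each metric over splits. With `max_mean = TRUE`, additionally
#' keeps only the classifier achieving the maximal mean of `metric` (the
#' "maximal mean performance over splits" reporting rule).
#'
#' @param records Data.frame of [metric_record()] rows.
#' @param metric Metric column used for max-mean selection.
#' @param max_mean If `TRUE`, return only the best configuration per the
#'   chosen metric.
#' @return Summary data.frame with `mean_*` and `se_*` columns.
#' @export
aggregate_splits <- function(records, metric = "accuracy", max_mean = FALSE) {
  if (nrow(records) == 0L) stop("no records")
  se <- function(v) if (length(v) < 2L) 0 else stats::sd(v) / sqrt(length(v))
  out <- do.call(rbind, lapply(split(records, records$classifier), function(r) {
    data.frame(classifier = r$classifier[1L], n_splits = nrow(r),
               mean_accuracy = mean(r$accuracy), se_accuracy = se(r$accuracy),
               mean_weighted_f1 = mean(r$weighted_f1), se_weighted_f1 = se(r$weighted_f1),
               mean_brier = mean(r$brier), se_brier = se(r$brier),
               n_single_class = sum(r$single_class))
  }))
  rownames(out) <- NULL
  if (max_mean) {
    col <- paste0("mean_", metric)
    best <- if (metric == "brier") which.min(out[[col]]) else which.max(out[[col]])
    out <- out[best, , drop = FALSE]
  }
  out
}

#' One-sided paired comparison of two classifiers
#'
#' Pairs records A and B by split id and tests whether A's mean `metric`
#' exceeds B's with a one-sided paired t-test. A zero-variance difference is
#' degenerate for the t statistic and reports p = 0 (A uniformly better),
#' p = 1 (uniformly worse) or p = 0.5 (identical).
#'
#' @param records_a,records_b Data.frames of [metric_record()] rows sharing
#'   split ids.
#' @param metric Metric column to compare.
#' @return The one-sided p-value.
#' @export
compare_classifiers <- function(records_a, records_b, metric = "weighted_f1") {
  a <- records_a[order(records_a$split), ]
  b <- records_b[order(records_b$split), ]
  if (!identical(as.character(a$split), as.character(b$split))) {
    stop("records are not paired by split id")
  }
  d <- a[[metric]] - b[[metric]]
  if (stats::sd(d) == 0) {
    return(if (mean(d) > 0) 0 else if (mean(d) < 0) 1 else 0.5)
  }
  stats::t.test(a[[metric]], b[[metric]], paired = TRUE,
                alternative = "greater")$p.value
}
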