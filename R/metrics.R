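# Confusion-matrix bookkeeping and derived classification metrics.

#' Confusion counts
#'
#' @param tp,tn,fp,fn nonnegative integer counts; their total must be
#'   positive.
#' @return an object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp = 0L, tn = 0L, fp = 0L, fn = 0L) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (sum(counts) <= 0) stop("total count must be positive")
  structure(as.list(as.integer(counts)), names = names(counts),
            class = "confusion_counts")
}

safe_ratio <- function(num, den) if (den > 0) num / den else NA_real_

#' Derived classification metrics
#'
#' Computes the nine standard derived metrics from the confusion counts:
#' sensitivity (TPR), specificity (SPC), precision (PPV), negative
#' predictive value (NPV), false positive rate (FPR), false discovery rate
#' (FDR = FP / (FP + TP)), false negative rate (FNR), accuracy (ACC) and F1.
#' A metric with a zero denominator is reported as `NA` (undefined), never
#' as 0.
#'
#' @param counts a [confusion_counts()] object.
#' @return an object of class `metric_set` (a named list of fractions).
#' @examples
#' compute_metrics(confusion_counts(tp = 169, tn = 615, fn = 49, fp = 27))
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  structure(list(
    sensitivity = safe_ratio(tp, tp + fn),
    specificity = safe_ratio(tn, fp + tn),
    precision   = safe_ratio(tp, tp + fp),
    npv         = safe_ratio(tn, tn + fn),
    fpr         = safe_ratio(fp, fp + tn),
    fdr         = safe_ratio(fp, fp + tp),
    fnr         = safe_ratio(fn, fn + tp),
    accuracy    = safe_ratio(tp + tn, tp + tn + fp + fn),
    f1          = safe_ratio(2 * tp, 2 * tp + fp + fn),
    counts      = counts),
    class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  for (m in setdiff(names(x), "counts"))
    cat(sprintf("  %-12s %s\n", m,
                if (is.na(x[[m]])) "undefined" else sprintf("%.4f", x[[m]])))
  invisible(x)
}

#' Classify one detection outcome
#'
#' Scores a [detect_fracture()] report against optional ground truth. A true
#' positive requires the image to be flagged *and* at least one detection
#' circle on the correct bone to contain the true fracture row; a flagged
#' image whose circles all miss the truth counts as a false negative. With
#' no true fracture, any flag is a false positive.
#'
#' @param report a `fracture_report`.
#' @param truth `NULL` (fracture-free) or a list with `row` (in the same
#'   coordinate frame as the report) and `bone_index` (0/1; bone lines 1-2
#'   belong to bone 0, lines 3-4 to bone 1).
#' @return one of `"TP"`, `"FN"`, `"TN"`, `"FP"`.
#' @export
match_detection <- function(report, truth = NULL) {
  stopifnot(inherits(report, "fracture_report"))
  if (is.null(truth)) return(if (report$fractured) "FP" else "TN")
  if (!report$fractured) return("FN")
  d <- report$detections
  bone_of_line <- (d$bone_line - 1L) %/% 2L
  hit <- bone_of_line == truth$bone_index &
    abs(d$row - truth$row) <= d$radius
  if (any(hit)) "TP" else "FN"
}

#' Evaluate a batch of detection reports
#'
#' @param reports list of `fracture_report` objects.
#' @param truths list of ground truths (elements `NULL` for fracture-free
#'   images), parallel to `reports`.
#' @return a list with `counts` ([confusion_counts()]), `metrics`
#'   ([compute_metrics()]) and the per-image `outcomes`.
#' @export
evaluate_batch <- function(reports, truths) {
  stopifnot(length(reports) == length(truths))
  outcomes <- vapply(seq_along(reports), function(i)
    match_detection(reports[[i]], truths[[i]]), character(1))
  counts <- confusion_counts(tp = sum(outcomes == "TP"),
                             tn = sum(outcomes == "TN"),
                             fp = sum(outcomes == "FP"),
                             fn = sum(outcomes == "FN"))
  list(counts = counts, metrics = compute_metrics(counts), outcomes = outcomes)
}
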