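#' Area under the ROC curve (midrank Mann-Whitney estimator)
#'
#' Equals the trapezoidal area under the empirical ROC curve, with tied
#' scores contributing 1/2 per tied event/non-event pair. Invariant under
#' strictly increasing transforms of the scores.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary event indicators (0/1); both classes must occur.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# cumulative TP/FP counts at each distinct threshold, descending; the
# classification rule is score >= threshold -> predicted positive
threshold_counts <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  last <- which(!duplicated(s, fromLast = TRUE))   # last index per value
  data.frame(threshold = s[last],
             tp = cumsum(y)[last],
             fp = cumsum(1 - y)[last])
}

#' Youden-index cutoff for a score
#'
#' Scans every distinct observed score as a candidate threshold for the
#' rule "score >= threshold predicts an event" and returns the threshold
#' maximizing Youden's J = sensitivity + specificity - 1. Ties are broken
#' toward the lowest threshold, i.e. the most sensitive operating point.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary event indicators (0/1); both classes must occur.
#' @return A list with `threshold`, `j`, `sensitivity`, `specificity`.
#' @export
youden_cutoff <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  tc <- threshold_counts(scores, labels)
  sens <- tc$tp / n1
  spec <- (n0 - tc$fp) / n0
  j <- sens + spec - 1
  # thresholds are descending; the last max index is the lowest threshold
  best <- max(which(j == max(j)))
  list(threshold = tc$threshold[best], j = j[best],
       sensitivity = sens[best], specificity = spec[best])
}

#' Confusion matrix of binary predictions
#'
#' @param tp,fp,fn,tn Non-negative cell counts (true positive, false
#'   positive, false negative, true negative).
#' @return An object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0)) stop("confusion-matrix counts must be non-negative")
  structure(as.list(cells), class = "confusion_matrix")
}

#' @rdname confusion_matrix
#' @param predicted Binary predicted classes (0/1).
#' @param labels Binary event indicators (0/1).
#' @export
confusion_from_predictions <- function(predicted, labels) {
  stopifnot(length(predicted) == length(labels),
            all(predicted %in% c(0, 1)), all(labels %in% c(0, 1)))
  confusion_matrix(tp = sum(predicted == 1 & labels == 1),
                   fp = sum(predicted == 1 & labels == 0),
                   fn = sum(predicted == 0 & labels == 1),
                   tn = sum(predicted == 0 & labels == 0))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(predicted = c("event", "non-event"),
                              actual = c("event", "non-event")))
  print(m)
  invisible(x)
}

#' Thresholded classification metrics from a confusion matrix
#'
#' Sensitivity (recall), specificity, precision and F1 (harmonic mean of
#' precision and sensitivity). A metric with a zero denominator is
#' returned as `NA` (undefined), not 0; F1 is 0 when precision and
#' sensitivity are both defined and both zero, and `NA` when either is
#' undefined.
#'
#' @param cm A [confusion_matrix()].
#' @return An object of class `metric_set` with `sensitivity`,
#'   `specificity`, `precision`, `f1`.
#' @export
metrics_from_confusion <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- ratio(cm$tp, cm$tp + cm$fn)
  spec <- ratio(cm$tn, cm$tn + cm$fp)
  prec <- ratio(cm$tp, cm$tp + cm$fp)
  f1 <- if (is.na(sens) || is.na(prec)) NA_real_
        else if (sens + prec == 0) 0
        else 2 * prec * sens / (prec + sens)
  structure(list(sensitivity = sens, specificity = spec,
                 precision = prec, f1 = f1),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("sensitivity %.3f  specificity %.3f  precision %.3f  F1 %.3f\n",
              x$sensitivity, x$specificity, x$precision, x$f1))
  invisible(x)
}

#' Arithmetic average of metric sets across evaluation folds
#'
#' Cross-validation harness helper: averages each metric over folds,
#' ignoring folds where a metric is undefined.
#'
#' @param metric_sets A list of [metrics_from_confusion()] results.
#' @return A `metric_set` of per-metric means.
#' @export
average_metric_sets <- function(metric_sets) {
  stopifnot(length(metric_sets) > 0)
  out <- lapply(c("sensitivity", "specificity", "precision", "f1"),
                function(nm) {
                  v <- vapply(metric_sets, `[[`, numeric(1), nm)
                  mean(v, na.rm = TRUE)
                })
  names(out) <- c("sensitivity", "specificity", "precision", "f1")
  structure(out, class = "metric_set")
}

#' Net reclassification improvement between two binary classifiers
#'
#' Compares predicted classes of a baseline model (`pred_a`) and a new
#' model (`pred_b`). Among events, upward reclassification (0 to 1) is
#' credited and downward penalized; among non-events the reverse. The
#' integrated NRI is the sum of the two components; the usual asymptotic
#' z test gives a two-sided P value.
#'
#' @param pred_a,pred_b Binary predicted classes (0/1) of the two models.
#' @param labels Binary event indicators (0/1); both classes must occur.
#' @return An object of class `nri_result` with `nri_event`,
#'   `nri_nonevent`, `nri_integrated`, `z`, `p_two_sided`.
#' @export
nri <- function(pred_a, pred_b, labels) {
  stopifnot(length(pred_a) == length(labels),
            length(pred_b) == length(labels),
            all(pred_a %in% c(0, 1)), all(pred_b %in% c(0, 1)),
            all(labels %in% c(0, 1)))
  ev <- labels == 1
  n_e <- sum(ev)
  n_ne <- sum(!ev)
  if (n_e == 0 || n_ne == 0) stop("both classes must be present")
  up <- pred_b > pred_a
  down <- pred_b < pred_a
  nri_e <- (sum(up & ev) - sum(down & ev)) / n_e
  nri_ne <- (sum(down & !ev) - sum(up & !ev)) / n_ne
  total <- nri_e + nri_ne
  se <- sqrt((sum(up & ev) + sum(down & ev)) / n_e^2 +
               (sum(up & !ev) + sum(down & !ev)) / n_ne^2)
  z <- if (se > 0) total / se else 0
  structure(list(nri_event = nri_e, nri_nonevent = nri_ne,
                 nri_integrated = total, z = z,
                 p_two_sided = 2 * stats::pnorm(-abs(z))),
            class = "nri_result")
}

#' @export
print.nri_result <- function(x, ...) {
  cat(sprintf(
    "NRI: events %+.3f, non-events %+.3f, integrated %+.3f (z = %.2f, P = %.3g)\n",
    x$nri_event, x$nri_nonevent, x$nri_integrated, x$z, x$p_two_sided))
  invisible(x)
}
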