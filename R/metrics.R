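# Evaluation metrics: confusion-count ratios, overlap coefficients, Fleiss'
# kappa, and the reader-study summary arithmetic. Undefined denominators
# raise typed errors rather than returning silent zeros.

#' Confusion counts
#'
#' @param tp,tn,fp,fn nonnegative integer tallies (or pixel counts).
#' @return list of class ConfusionCounts.
#' @export
confusionCounts <- function(tp, tn, fp, fn) {
  v <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(v < 0) || any(!is.finite(v)))
    stopf("spineDSS_validation_error", "confusion counts must be finite and nonnegative")
  structure(as.list(v), class = "ConfusionCounts")
}

#' Pixel-wise confusion counts from two binary masks
#'
#' @param pred,truth binary matrices (or [HerniationMask-class]) of equal
#'   shape; nonzero is foreground.
#' @return a [confusionCounts()] object.
#' @export
confusionFromMasks <- function(pred, truth) {
  p <- if (is(pred, "HerniationMask")) maskMatrix(pred) else pred
  t_ <- if (is(truth, "HerniationMask")) maskMatrix(truth) else truth
  if (!all(dim(p) == dim(t_)))
    stopf("spineDSS_validation_error", "mask shapes differ: %s vs %s",
          paste(dim(p), collapse = "x"), paste(dim(t_), collapse = "x"))
  p <- p != 0; t_ <- t_ != 0
  confusionCounts(tp = sum(p & t_), tn = sum(!p & !t_),
                  fp = sum(p & !t_), fn = sum(!p & t_))
}

ratioOrError <- function(num, den, what) {
  if (den == 0)
    stopf("spineDSS_undefined_metric", "%s is undefined (zero denominator)", what)
  num / den
}

#' @rdname classificationMetrics
#' @export
specificity <- function(c) ratioOrError(c$tn, c$fp + c$tn, "specificity")

#' @rdname classificationMetrics
#' @export
sensitivity <- function(c) ratioOrError(c$tp, c$tp + c$fn, "sensitivity")

#' @rdname classificationMetrics
#' @export
precision <- function(c) ratioOrError(c$tp, c$tp + c$fp, "precision")

#' Classification metrics from confusion counts
#'
#' Specificity TN/(FP+TN), sensitivity TP/(TP+FN), precision TP/(TP+FP),
#' accuracy (TP+TN)/total, Dice similarity coefficient 2TP/(FP+2TP+FN) and
#' intersection-over-union TP/(FP+TP+FN). A zero denominator raises a typed
#' \code{spineDSS_undefined_metric} error.
#'
#' @param c a [confusionCounts()] object.
#' @name classificationMetrics
#' @export
accuracy <- function(c) ratioOrError(c$tp + c$tn, c$tp + c$tn + c$fp + c$fn, "accuracy")

#' @rdname classificationMetrics
#' @export
dsc <- function(c) ratioOrError(2 * c$tp, c$fp + 2 * c$tp + c$fn, "DSC")

#' @rdname classificationMetrics
#' @export
iou <- function(c) ratioOrError(c$tp, c$fp + c$tp + c$fn, "IoU")

#' Fleiss' kappa
#'
#' Chance-corrected agreement for n raters assigning N items to k
#' categories, from the N x k table of per-item category counts (constant
#' row sum n >= 2). Returns exactly 1 when every item is rated unanimously.
#'
#' @param counts N x k matrix of rating counts.
#' @return the kappa statistic.
#' @examples
#' fleissKappa(rbind(c(3, 0), c(1, 2)))  # 0.25
#' @export
fleissKappa <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 1 || any(counts < 0))
    stopf("spineDSS_validation_error", "counts must be a nonnegative N x k matrix")
  rs <- rowSums(counts)
  if (length(unique(rs)) != 1)
    stopf("spineDSS_validation_error", "all items must be rated by the same number of raters")
  n <- rs[1]
  if (n < 2)
    stopf("spineDSS_validation_error", "need at least 2 raters")
  N <- nrow(counts)
  Pi <- (rowSums(counts^2) - n) / (n * (n - 1))
  Pbar <- mean(Pi)
  if (Pbar == 1) return(1)
  pj <- colSums(counts) / (N * n)
  Pe <- sum(pj^2)
  (Pbar - Pe) / (1 - Pe)
}

#' Reader-study summary arithmetic
#'
#' Per-task relative accuracy improvement (assisted - unassisted) /
#' unassisted and relative time reduction (unassisted - assisted) /
#' unassisted, plus cross-task means; the report columns are percentages
#' rounded to 2 decimals (means are taken before rounding).
#'
#' @param unassisted,assisted data.frames with columns \code{task},
#'   \code{accuracy}, \code{time} (matched row order).
#' @return list with \code{perTask} data.frame,
#'   \code{meanAccuracyImprovedPct} and \code{meanTimeReductionPct}.
#' @examples
#' readerStudySummary(
#'   data.frame(task = "diagnosis", accuracy = 61.67, time = 496.5),
#'   data.frame(task = "diagnosis", accuracy = 77.00, time = 321.8))
#' @export
readerStudySummary <- function(unassisted, assisted) {
  if (nrow(unassisted) != nrow(assisted) ||
      !identical(as.character(unassisted$task), as.character(assisted$task)))
    stopf("spineDSS_validation_error", "unassisted and assisted tasks must match")
  imp <- 100 * (assisted$accuracy - unassisted$accuracy) / unassisted$accuracy
  red <- 100 * (unassisted$time - assisted$time) / unassisted$time
  list(perTask = data.frame(task = unassisted$task,
                            accuracyImprovedPct = round(imp, 2),
                            timeReductionPct = round(red, 2)),
       meanAccuracyImprovedPct = round(mean(imp), 2),
       meanTimeReductionPct = round(mean(red), 2))
}

#' One-vs-rest per-class metrics for a multi-class task
#'
#' Per-class precision and sensitivity (one-vs-rest) plus micro accuracy
#' (trace over total), in the style of a per-grade performance table.
#'
#' @param pred,truth equal-length vectors of class labels.
#' @param classes class order; defaults to sorted union.
#' @return list(perClass data.frame, accuracy).
#' @export
multiclassMetrics <- function(pred, truth, classes = sort(unique(c(pred, truth)))) {
  if (length(pred) != length(truth))
    stopf("spineDSS_validation_error", "pred and truth lengths differ")
  tab <- table(factor(pred, classes), factor(truth, classes))
  per <- data.frame(class = classes,
                    precision = NA_real_, sensitivity = NA_real_)
  for (k in seq_along(classes)) {
    tp <- tab[k, k]
    per$precision[k] <- if (sum(tab[k, ]) > 0) tp / sum(tab[k, ]) else NA_real_
    per$sensitivity[k] <- if (sum(tab[, k]) > 0) tp / sum(tab[, k]) else NA_real_
  }
  list(perClass = per, accuracy = sum(diag(tab)) / sum(tab), table = tab)
}
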