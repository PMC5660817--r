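#' Pixelwise confusion counts between two binary masks
#'
#' @param truth,pred binary 0/1 matrices of identical shape; `truth` is the
#'   reference segmentation.
#' @return Object of class `confusion_counts` with fields `tp`, `fp`, `fn`,
#'   `tn` (summing to the number of pixels).
#' @export
confusion_counts <- function(truth, pred) {
  check_binary_mask(truth, "truth")
  check_binary_mask(pred, "pred")
  if (!identical(dim(truth), dim(pred)))
    stop_input("truth and pred must have identical shapes")
  t1 <- truth > 0; p1 <- pred > 0
  structure(list(tp = sum(t1 & p1), fp = sum(!t1 & p1),
                 fn = sum(t1 & !p1), tn = sum(!t1 & !p1)),
            class = "confusion_counts")
}

#' Overlap and success/error metrics
#'
#' Jaccard `R = TP/(TP+FP+FN)`, Dice `D = 2TP/(2TP+FP+FN)` (equivalently
#' `2|T∩S|/(|T|+|S|)`), sensitivity `Se = TP/(TP+FN)` and specificity
#' `Sp = TN/(TN+FP)` with the true negatives counted over the full image
#' grid. A zero denominator yields `NA` rather than an error.
#'
#' @param counts a [confusion_counts()] object, or a truth mask when `pred`
#'   is supplied.
#' @param pred optional prediction mask (convenience form).
#' @return Object of class `metrics_record` with fields `dice`, `jaccard`,
#'   `sensitivity`, `specificity` and the counts.
#' @export
overlap_metrics <- function(counts, pred = NULL) {
  if (!is.null(pred)) counts <- confusion_counts(counts, pred)
  stopifnot(inherits(counts, "confusion_counts"))
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  with(counts, structure(list(
    dice = safe_div(2 * tp, 2 * tp + fp + fn),
    jaccard = safe_div(tp, tp + fp + fn),
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    tp = tp, fp = fp, fn = fn, tn = tn), class = "metrics_record"))
}

#' @export
print.metrics_record <- function(x, ...) {
  cat(sprintf("Dice %.4f | Jaccard %.4f | Se %.4f | Sp %.4f\n",
              x$dice, x$jaccard, x$sensitivity, x$specificity))
  cat(sprintf("TP %d  FP %d  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' @export
as.data.frame.metrics_record <- function(x, ...) {
  data.frame(dice = x$dice, jaccard = x$jaccard, sensitivity = x$sensitivity,
             specificity = x$specificity, tp = x$tp, fp = x$fp, fn = x$fn,
             tn = x$tn)
}
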