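#' Binarize an 8-bit probability volume
#'
#' Segmentation outputs are compared after binarizing the 0-255 probability
#' volume at a threshold of 200 (inclusive).
#'
#' @param prob8 Numeric 3D array with values in `[0, 255]`.
#' @param threshold Inclusive binarization level (default 200).
#' @return Logical 3D array.
#' @export
binarize_prob <- function(prob8, threshold = 200) {
  assert_volume(prob8)
  array(prob8 >= threshold, dim(prob8))
}

#' Voxel-wise segmentation metrics
#'
#' Confusion counts and the four standard overlap ratios:
#' precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, their harmonic mean F1, and
#' Jaccard `TP/(TP+FP+FN)`. Ratios with a zero denominator are reported as
#' 0 and flagged in `$undefined`, so batch evaluation stays total.
#'
#' @param pred Predicted mask (logical or 0/1 array).
#' @param gt Ground-truth mask of the same shape.
#' @return A list of class `"seg_metrics"` with `tp`, `fp`, `fn`, `tn`,
#'   `precision`, `recall`, `f1`, `jaccard` and `undefined`.
#' @examples
#' gt <- array(c(rep(TRUE, 8), rep(FALSE, 19)), c(3, 3, 3))
#' pr <- array(c(rep(TRUE, 6), rep(FALSE, 2), rep(TRUE, 2), rep(FALSE, 17)),
#'             c(3, 3, 3))
#' seg_metrics(pr, gt)
#' @export
seg_metrics <- function(pred, gt) {
  assert_mask(pred); assert_mask(gt)
  same_shape(pred, gt, "pred and gt")
  p <- as.logical(pred); g <- as.logical(gt)
  tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g); tn <- sum(!p & !g)
  undefined <- character(0)
  ratio <- function(num, den, what) {
    if (den == 0) { undefined <<- c(undefined, what); return(0) }
    num / den
  }
  precision <- ratio(tp, tp + fp, "precision")
  recall <- ratio(tp, tp + fn, "recall")
  f1 <- ratio(2 * precision * recall, precision + recall, "f1")
  jaccard <- ratio(tp, tp + fp + fn, "jaccard")
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 precision = precision, recall = recall, f1 = f1,
                 jaccard = jaccard, undefined = undefined),
            class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat(sprintf("Voxel-wise segmentation metrics (TP %d, FP %d, FN %d, TN %d)\n",
              x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  precision %.4f  recall %.4f  F1 %.4f  Jaccard %.4f\n",
              x$precision, x$recall, x$f1, x$jaccard))
  if (length(x$undefined))
    cat("  undefined (0/0, reported as 0):", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

# Dice coefficient between two masks (used for label-stability convergence)
dice_coef <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}
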