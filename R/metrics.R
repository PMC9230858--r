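# Segmentation-quality metrics and patient-level cross-validation splits
# for the CNN arm (and for judging any mask against ground truth).

#' Voxelwise confusion counts between two binary volumes
#'
#' Positive means rib voxel (value 255); counts run over all voxels of
#' the common grid.
#'
#' @param pred,truth [binary_volume()]s with identical geometry.
#' @return An object of class `confusion_counts` with elements `TP`,
#'   `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(pred, truth) {
  stopifnot(inherits(pred, "binary_volume"), inherits(truth, "binary_volume"))
  if (!same_geometry(pred, truth))
    stop("parameter error: prediction and truth geometries differ", call. = FALSE)
  p <- pred$voxels == 255L
  t <- truth$voxels == 255L
  structure(list(TP = sum(p & t), FP = sum(p & !t),
                 TN = sum(!p & !t), FN = sum(!p & t)),
            class = "confusion_counts")
}

#' Segmentation metrics from confusion counts
#'
#' Dice similarity coefficient `2TP / ((TP+FP) + (TP+FN))`, precision
#' `TP / (TP+FP)`, recall `TP / (TP+FN)`, specificity `TN / (TN+FP)` and
#' accuracy `(TP+TN) / total`.  A metric whose denominator is zero is
#' reported as `NA` (undefined), not 0.
#'
#' @param counts a `confusion_counts` (or list with TP/FP/TN/FN).
#' @return An object of class `seg_metrics` with elements `dsc`,
#'   `precision`, `recall`, `specificity`, `accuracy`.
#' @export
compute_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  if (any(c(TP, FP, TN, FN) < 0)) stop("parameter error: negative counts", call. = FALSE)
  div <- function(num, den) if (den > 0) num / den else NA_real_
  total <- TP + FP + TN + FN
  structure(list(dsc = div(2 * TP, (TP + FP) + (TP + FN)),
                 precision = div(TP, TP + FP),
                 recall = div(TP, TP + FN),
                 specificity = div(TN, TN + FP),
                 accuracy = div(TP + TN, total)),
            class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat(sprintf("<seg_metrics> DSC %.3f | precision %.3f | recall %.3f | specificity %.3f | accuracy %.3f\n",
              x$dsc, x$precision, x$recall, x$specificity, x$accuracy))
  invisible(x)
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d, FP %d, TN %d, FN %d\n",
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Patient-level k-fold split
#'
#' Partitions case identifiers into k folds; each case appears in exactly
#' one test fold.  Deterministic given the seed; fold sizes differ by at
#' most one.
#'
#' @param case_ids vector of case identifiers.
#' @param k number of folds.
#' @param seed integer seed for the shuffle.
#' @return List of k elements, each `list(train = ..., test = ...)`.
#' @export
kfold_split <- function(case_ids, k, seed = 1L) {
  n <- length(case_ids)
  if (k > n) stop("parameter error: k exceeds the number of cases", call. = FALSE)
  if (k < 2L) stop("parameter error: k must be at least 2", call. = FALSE)
  perm <- with_local_seed(as.integer(seed), sample.int(n))
  fold <- rep(seq_len(k), length.out = n)  # round-robin over the shuffle
  lapply(seq_len(k), function(i) {
    test <- case_ids[perm[fold == i]]
    list(train = setdiff(case_ids, test), test = test)
  })
}
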