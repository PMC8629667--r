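#' Confusion counts between a predicted and a reference mask
#'
#' @param pred,truth Binary (0/1) matrices of the same shape.
#' @return A named list with counts `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(pred, truth) {
  assert_binary(pred, "pred"); assert_binary(truth, "truth")
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth must have the same shape", call. = FALSE)
  p <- pred == 1; t <- truth == 1
  list(tp = sum(p & t), tn = sum(!p & !t), fp = sum(p & !t), fn = sum(!p & t))
}

#' Segmentation accuracy from confusion counts
#'
#' `(tp + tn) / (tp + tn + fp + fn)` — the fraction of correctly labelled
#' pixels.
#'
#' @param counts A list as returned by [confusion_counts()].
#' @return A scalar in \[0, 1\].
#' @export
seg_accuracy <- function(counts) {
  tot <- counts$tp + counts$tn + counts$fp + counts$fn
  if (tot <= 0) stop("empty input: zero total count", call. = FALSE)
  (counts$tp + counts$tn) / tot
}

#' Jaccard overlap coefficient
#'
#' `|intersection(M, N)| / (|M| + |N| - |intersection(M, N)|)`. Two empty masks have
#' similarity 1 by convention; one empty mask against a non-empty one gives 0.
#'
#' @param mask_m,mask_n Binary (0/1) matrices of the same shape.
#' @return A scalar in \[0, 1\].
#' @export
jaccard <- function(mask_m, mask_n) {
  assert_binary(mask_m, "mask_m"); assert_binary(mask_n, "mask_n")
  if (!identical(dim(mask_m), dim(mask_n)))
    stop("masks must have the same shape", call. = FALSE)
  inter <- sum(mask_m == 1 & mask_n == 1)
  uni <- sum(mask_m) + sum(mask_n) - inter
  if (uni == 0) return(1)
  inter / uni
}

#' Dice overlap coefficient
#'
#' `2 |intersection(Y, Z)| / (|Y| + |Z|)`. The `union_denominator` variant divides
#' by the union size instead (that form can exceed 1 and is provided for
#' comparison only).
#'
#' @param mask_y,mask_z Binary (0/1) matrices of the same shape.
#' @param union_denominator Use the union size as the denominator.
#' @return A non-negative scalar (in \[0, 1\] for the standard form).
#' @export
dice <- function(mask_y, mask_z, union_denominator = FALSE) {
  assert_binary(mask_y, "mask_y"); assert_binary(mask_z, "mask_z")
  if (!identical(dim(mask_y), dim(mask_z)))
    stop("masks must have the same shape", call. = FALSE)
  inter <- sum(mask_y == 1 & mask_z == 1)
  den <- if (union_denominator) sum(mask_y) + sum(mask_z) - inter
         else sum(mask_y) + sum(mask_z)
  if (den == 0) return(1)
  2 * inter / den
}

#' All segmentation metrics for one mask pair
#'
#' @param pred,truth Binary (0/1) matrices of the same shape.
#' @return A one-row data frame with the confusion counts and the accuracy,
#'   Jaccard and Dice coefficients.
#' @export
seg_metrics <- function(pred, truth) {
  cc <- confusion_counts(pred, truth)
  data.frame(tp = cc$tp, tn = cc$tn, fp = cc$fp, fn = cc$fn,
             accuracy = seg_accuracy(cc),
             jaccard = jaccard(pred, truth),
             dice = dice(pred, truth))
}
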