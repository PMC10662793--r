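#' Dice overlap coefficient
#'
#' `2 |A ∩ B| / (|A| + |B|)`: 1 when the masks are identical, 0 when
#' they are disjoint.  Two empty masks are defined to agree perfectly
#' (Dice 1).
#'
#' @param A,B logical arrays of the same shape.
#' @return The Dice coefficient in `[0, 1]`.
#' @examples
#' a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
#' b <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2)
#' dice(a, b)  # |A|=|B|=2, overlap 1 -> 0.5
#' @export
dice <- function(A, B) {
  check_same_shape(A, B)
  na <- sum(A); nb <- sum(B)
  if (na + nb == 0L) return(1)
  2 * sum(A & B) / (na + nb)
}

#' Pixelwise recall and precision
#'
#' Standard overlap scores of a predicted mask against ground truth:
#' recall `tp / (tp + fn)` and precision `tp / (tp + fp)`.  Precision is
#' undefined (`NaN`) for an empty prediction.
#'
#' @param pred,truth logical arrays of the same shape.
#' @return An object of class `overlap_scores` with `dice`, `recall`,
#'   `precision` and the `tp`/`fp`/`fn` counts.
#' @export
overlap_scores <- function(pred, truth) {
  check_same_shape(pred, truth)
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  structure(list(
    dice = if (2 * tp + fp + fn == 0L) 1 else 2 * tp / (2 * tp + fp + fn),
    recall = if (tp + fn == 0L) 1 else tp / (tp + fn),
    precision = if (tp + fp == 0L) NaN else tp / (tp + fp),
    tp = tp, fp = fp, fn = fn), class = "overlap_scores")
}

#' @rdname overlap_scores
#' @export
recall_precision <- overlap_scores

#' @export
print.overlap_scores <- function(x, ...) {
  cat(sprintf("<overlap_scores> dice %.4f, recall %.4f, precision %s (tp %d, fp %d, fn %d)\n",
              x$dice, x$recall,
              if (is.nan(x$precision)) "NaN" else sprintf("%.4f", x$precision),
              x$tp, x$fp, x$fn))
  invisible(x)
}

check_same_shape <- function(A, B) {
  if (!is.logical(A) || !is.logical(B) || is.null(dim(A)) || is.null(dim(B)))
    stop("masks must be logical arrays")
  if (!identical(dim(A), dim(B)))
    stop("mask shapes differ: ", paste(dim(A), collapse = "x"), " vs ",
         paste(dim(B), collapse = "x"))
  invisible(TRUE)
}
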