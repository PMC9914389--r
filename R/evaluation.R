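# Pixel-based evaluation with vessel as the positive class.

#' Pixelwise confusion counts between a prediction and ground truth
#'
#' Optionally restricted to a field-of-view mask (pixels outside the FOV
#' are ignored entirely).
#'
#' @param gt binary \{0,1\} ground-truth mask (1 = vessel).
#' @param pred binary \{0,1\} predicted mask.
#' @param fov optional binary FOV mask of the same shape.
#' @return a [ConfusionCounts-class].
#' @export
confusionCounts <- function(gt, pred, fov = NULL) {
  stopifnotShape(gt, pred)
  if (!all(gt %in% c(0L, 1L)) || !all(pred %in% c(0L, 1L)))
    stop("masks must be two-valued {0,1}")
  if (!is.null(fov)) {
    stopifnotShape(gt, fov, "fov and masks")
    keep <- fov == 1L
    gt <- gt[keep]; pred <- pred[keep]
  }
  tp <- sum(gt == 1L & pred == 1L)
  tn <- sum(gt == 0L & pred == 0L)
  fp <- sum(gt == 0L & pred == 1L)
  fn <- sum(gt == 1L & pred == 0L)
  new("ConfusionCounts", tp = as.integer(tp), tn = as.integer(tn),
      fp = as.integer(fp), fn = as.integer(fn))
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' `sen = 100 tp / (tp + fn)`, `spec = 100 tn / (tn + fp)`,
#' `acc = 100 (tp + tn) / (tp + tn + fp + fn)`, all in percent. A metric
#' whose denominator is zero is reported as `NA` with a warning rather
#' than 0.
#'
#' @param counts a [ConfusionCounts-class].
#' @return named list with elements `sen`, `spec`, `acc` (percent) and the
#'   four counts.
#' @export
segMetrics <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  tp <- counts@tp; tn <- counts@tn; fp <- counts@fp; fn <- counts@fn
  sen <- if (tp + fn > 0) 100 * tp / (tp + fn) else {
    warning("sensitivity undefined: no positive ground-truth pixels"); NA_real_
  }
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else {
    warning("specificity undefined: no negative ground-truth pixels"); NA_real_
  }
  total <- tp + tn + fp + fn
  acc <- if (total > 0) 100 * (tp + tn) / total else {
    warning("accuracy undefined: no evaluated pixels"); NA_real_
  }
  list(sen = sen, spec = spec, acc = acc, tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Mapping coefficient between ground truth and an extracted mask
#'
#' `MAPC = |GT intersect SM| / (|GT| + |SM|)` — half the Dice coefficient,
#' ranging over \[0, 0.5\] with 0.5 exactly when the masks agree and are
#' non-empty. Two empty masks give 0 with a warning (0/0 convention).
#'
#' @param gt,sm binary \{0,1\} masks of the same shape.
#' @return scalar in \[0, 0.5\].
#' @export
mapCoefficientMasks <- function(gt, sm) {
  stopifnotShape(gt, sm)
  nGT <- sum(gt == 1L); nSM <- sum(sm == 1L)
  if (nGT + nSM == 0L) {
    warning("both masks empty: MAPC defined as 0")
    return(0)
  }
  sum(gt == 1L & sm == 1L) / (nGT + nSM)
}
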