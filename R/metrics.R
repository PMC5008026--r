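# Evaluation metrics: confusion-matrix statistics, volume overlap metrics
# (VOE, SRVD), symmetric surface distances (ASD, RMSD, MSD), Dice, and the
# threshold-accuracy sweep experiment.

#' Confusion-matrix metrics for a mask pair
#'
#' Pixel-wise confusion counts of a predicted against a reference liver mask
#' and the derived ratios: sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, accuracy `(TP+TN)/(P+N)`. Ratios whose denominator is zero
#' (e.g. sensitivity with an empty reference) are `NA` and listed in the
#' report's `undefined` field rather than silently coerced.
#'
#' @param pred,ref Integer 0/1 matrices of identical shape (prediction,
#'   reference).
#' @return An object of class `seg_report` with fields `tp`, `tn`, `fp`,
#'   `fn`, `sensitivity`, `specificity`, `accuracy`, `undefined`.
#' @export
confusion_metrics <- function(pred, ref) {
  pred <- as_binary_mask(pred); ref <- as_binary_mask(ref)
  if (!all(dim(pred) == dim(ref)))
    stop("pred and ref must have the same shape", call. = FALSE)
  tp <- sum(pred == 1L & ref == 1L)
  tn <- sum(pred == 0L & ref == 0L)
  fp <- sum(pred == 1L & ref == 0L)
  fn <- sum(pred == 0L & ref == 1L)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  rep <- list(tp = tp, tn = tn, fp = fp, fn = fn,
              sensitivity = ratio(tp, tp + fn),
              specificity = ratio(tn, tn + fp),
              accuracy = ratio(tp + tn, tp + tn + fp + fn))
  rep$undefined <- names(which(vapply(
    rep[c("sensitivity", "specificity", "accuracy")], is.na, logical(1))))
  structure(rep, class = "seg_report")
}

#' Volumetric overlap metrics
#'
#' `VOE = 100 * (1 - |A∩B| / |A∪B|)` (volumetric overlap error, a percentage
#' of the union) and `SRVD = 100 * (|A| - |B|) / |B|` (signed relative volume
#' difference; positive means oversegmentation), with `A` the prediction and
#' `B` the reference, following the MICCAI 2007 liver segmentation challenge
#' conventions.
#'
#' @inheritParams confusion_metrics
#' @return Named list with `voe` and `srvd`, both in percent.
#' @export
volume_metrics <- function(pred, ref) {
  pred <- as_binary_mask(pred); ref <- as_binary_mask(ref)
  if (!all(dim(pred) == dim(ref)))
    stop("pred and ref must have the same shape", call. = FALSE)
  nb <- sum(ref)
  if (nb == 0) stop("reference mask is empty", call. = FALSE)
  na <- sum(pred)
  inter <- sum(pred == 1L & ref == 1L)
  uni <- na + nb - inter
  list(voe = 100 * (1 - inter / uni), srvd = 100 * (na - nb) / nb)
}

#' Dice overlap coefficient
#'
#' `2 |A∩B| / (|A| + |B|)`.
#'
#' @inheritParams confusion_metrics
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(pred, ref) {
  pred <- as_binary_mask(pred); ref <- as_binary_mask(ref)
  if (!all(dim(pred) == dim(ref)))
    stop("pred and ref must have the same shape", call. = FALSE)
  s <- sum(pred) + sum(ref)
  if (s == 0) stop("both masks are empty", call. = FALSE)
  2 * sum(pred == 1L & ref == 1L) / s
}

# Border pixels: positive pixels with at least one background 4-neighbor
# (pixels on the image edge count as border).
border_pixels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  nbmin <- pmin(pad[1:nr, 2:(nc + 1)], pad[3:(nr + 2), 2:(nc + 1)],
                pad[2:(nr + 1), 1:nc], pad[2:(nr + 1), 3:(nc + 2)])
  which(core == 1L & nbmin == 0L, arr.ind = TRUE)
}

# Directed nearest-neighbor distances from each point of a to the set b,
# in mm; coordinates are (row, col) pixel indices scaled by spacing.
directed_nn <- function(a, b, spacing) {
  ar <- a[, 1] * spacing[1]; ac <- a[, 2] * spacing[2]
  br <- b[, 1] * spacing[1]; bc <- b[, 2] * spacing[2]
  out <- numeric(nrow(a))
  chunk <- max(1L, floor(2e7 / nrow(b)))
  for (s in seq(1, nrow(a), by = chunk)) {
    e <- min(s + chunk - 1, nrow(a))
    d2 <- outer(ar[s:e], br, "-")^2 + outer(ac[s:e], bc, "-")^2
    out[s:e] <- sqrt(apply(d2, 1, min))
  }
  out
}

#' Symmetric surface distance metrics
#'
#' Border pixels of each mask (positive pixels with a background 4-neighbor)
#' are extracted, the two directed nearest-neighbor distance sets (prediction
#' border to reference border, and vice versa) are pooled in millimetres,
#' and the mean (ASD), root mean square (RMSD) and maximum (MSD) of the
#' pooled set are returned. Anisotropic pixel spacing is honored.
#'
#' @inheritParams confusion_metrics
#' @param spacing Length-2 numeric (row, col) pixel size in mm.
#' @return Named list with `asd`, `rmsd`, `msd` in mm.
#' @export
surface_distance_metrics <- function(pred, ref, spacing = c(1, 1)) {
  pred <- as_binary_mask(pred); ref <- as_binary_mask(ref)
  if (!all(dim(pred) == dim(ref)))
    stop("pred and ref must have the same shape", call. = FALSE)
  if (sum(pred) == 0 || sum(ref) == 0)
    stop("surface distances require two non-empty masks", call. = FALSE)
  bp <- border_pixels(pred); br <- border_pixels(ref)
  pooled <- c(directed_nn(bp, br, spacing), directed_nn(br, bp, spacing))
  list(asd = mean(pooled), rmsd = sqrt(mean(pooled^2)), msd = max(pooled))
}

#' Full segmentation report
#'
#' Combines [confusion_metrics()], [volume_metrics()] and
#' [surface_distance_metrics()] into one `seg_report`.
#'
#' @inheritParams surface_distance_metrics
#' @return A `seg_report` with confusion counts, ratio metrics, `voe`,
#'   `srvd` (percent) and `asd`, `rmsd`, `msd` (mm).
#' @export
evaluate_segmentation <- function(pred, ref, spacing = c(1, 1)) {
  rep <- confusion_metrics(pred, ref)
  vm <- volume_metrics(pred, ref)
  sm <- surface_distance_metrics(pred, ref, spacing)
  rep[names(vm)] <- vm
  rep[names(sm)] <- sm
  rep$spacing <- as.numeric(spacing)
  class(rep) <- "seg_report"
  rep
}

#' @export
print.seg_report <- function(x, ...) {
  cat("Segmentation report\n")
  cat(sprintf("  TP %d  FP %d  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.4f", v)
  cat(sprintf("  sensitivity %s  specificity %s  accuracy %s\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$accuracy)))
  if (!is.null(x$voe))
    cat(sprintf("  VOE %.2f%%  SRVD %+.2f%%\n", x$voe, x$srvd))
  if (!is.null(x$asd))
    cat(sprintf("  ASD %.3f mm  RMSD %.3f mm  MSD %.3f mm\n",
                x$asd, x$rmsd, x$msd))
  invisible(x)
}

#' Threshold-accuracy sweep
#'
#' Runs the full segmentation at each threshold over a set of phantoms (or
#' any image/truth pairs) and reports the mean pixel accuracy per threshold.
#' A segmentation failure at some threshold (e.g. no edge evidence at an
#' extreme T) is scored as an empty prediction rather than aborting the
#' sweep, mirroring how a failed case would enter an accuracy average.
#'
#' @param phantom_set List of items, each a list with elements `slice` (a
#'   [ct_slice()]) and `truth` (0/1 matrix), as produced by
#'   [generate_suite()].
#' @param t_values Numeric vector of thresholds to test.
#' @param params Baseline [sblda_params()]; `T` is overridden per sweep
#'   point.
#' @param apply_ring_mask Passed through to [segment_liver()].
#' @return A data frame with columns `T` and `mean_accuracy`, and the
#'   per-phantom accuracy matrix as attribute `"accuracy"`.
#' @export
threshold_sweep <- function(phantom_set, t_values, params = sblda_params(),
                            apply_ring_mask = TRUE) {
  stopifnot(length(phantom_set) >= 1, length(t_values) >= 1)
  acc <- matrix(NA_real_, length(t_values), length(phantom_set))
  for (i in seq_along(t_values)) {
    p <- params
    p$T <- t_values[i]
    for (j in seq_along(phantom_set)) {
      item <- phantom_set[[j]]
      pred <- tryCatch(
        segment_liver(item$slice, p, apply_ring_mask = apply_ring_mask),
        error = function(e) matrix(0L, nrow(item$truth), ncol(item$truth)))
      acc[i, j] <- confusion_metrics(pred, item$truth)$accuracy
    }
  }
  out <- data.frame(T = t_values, mean_accuracy = rowMeans(acc))
  attr(out, "accuracy") <- acc
  out
}
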