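#' Pixelwise confusion counts between two binary masks
#'
#' @param pred,gt binary matrices (or arrays) of identical dimensions;
#'   `gt` is the ground truth.
#' @return List with integer fields `TP`, `FP`, `TN`, `FN` summing to the
#'   pixel count.
#' @export
confusion_counts <- function(pred, gt) {
  check_mask_pair(pred, gt)
  p <- as.logical(pred); g <- as.logical(gt)
  list(TP = sum(p & g), FP = sum(p & !g), TN = sum(!p & !g), FN = sum(!p & g))
}

check_mask_pair <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt))) {
    stop_suvseg("prediction and ground truth must have identical dimensions",
                class = "suvseg_format_error")
  }
  if (!is_binary(pred) || !is_binary(gt)) {
    stop_suvseg("masks must be binary (values in {0, 1})",
                class = "suvseg_format_error")
  }
  invisible(TRUE)
}

#' True positive rate (sensitivity)
#'
#' `TPR = TP / (TP + FN)`: the fraction of ground-truth foreground pixels
#' recovered by the prediction. Undefined (`NA`) when the ground truth has
#' no foreground; undefined values are excluded from cohort means.
#'
#' @param c confusion counts from [confusion_counts()].
#' @return Scalar in \[0, 1\] or `NA`.
#' @export
tpr <- function(c) if ((c$TP + c$FN) == 0) NA_real_ else c$TP / (c$TP + c$FN)

#' True negative rate (specificity)
#'
#' `TNR = TN / (TN + FP)`: the fraction of ground-truth background pixels
#' correctly labelled background. Undefined (`NA`) when the ground truth
#' has no background.
#'
#' @param c confusion counts from [confusion_counts()].
#' @return Scalar in \[0, 1\] or `NA`.
#' @export
tnr <- function(c) if ((c$TN + c$FP) == 0) NA_real_ else c$TN / (c$TN + c$FP)

#' Dice-Sorensen coefficient
#'
#' `DSC = 2 |Sg intersect Sp| / (|Sg| + |Sp|)`, the standard overlap metric
#' for medical image segmentation; 1 is a perfect match. Undefined (`NA`)
#' when both masks are empty.
#'
#' @param pred,gt binary masks of identical dimensions.
#' @return Scalar in \[0, 1\] or `NA`.
#' @export
dsc <- function(pred, gt) {
  check_mask_pair(pred, gt)
  denom <- sum(pred != 0) + sum(gt != 0)
  if (denom == 0) return(NA_real_)
  2 * sum(pred != 0 & gt != 0) / denom
}

#' Directed Hausdorff distance between two point sets
#'
#' `h(A, B) = max over a in A of min over b in B of ||a - b||` (Euclidean):
#' the worst-case distance from a point of A to its nearest point of B.
#' Generally asymmetric.
#'
#' @param A,B numeric matrices of point coordinates, one point per row,
#'   same number of columns; both nonempty.
#' @return Scalar distance (same units as the coordinates).
#' @export
directed_hausdorff <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) == 0L || nrow(B) == 0L) {
    stop_suvseg("directed_hausdorff requires nonempty point sets",
                class = "suvseg_degenerate_error")
  }
  # ||a-b||^2 = |a|^2 + |b|^2 - 2 a.b, minimized over B in one GEMM
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  cross <- A %*% t(B)
  d2 <- sweep(-2 * cross, 2, b2, `+`) + a2
  sqrt(max(pmax(apply(d2, 1, min), 0)))
}

#' Symmetric Hausdorff distance
#'
#' `HD(A, B) = max(h(A, B), h(B, A))`. Sensitive to outliers by design: a
#' single stray point moves the maximum.
#'
#' @inheritParams directed_hausdorff
#' @return Scalar distance.
#' @export
hausdorff <- function(A, B) {
  max(directed_hausdorff(A, B), directed_hausdorff(B, A))
}

#' Foreground pixel coordinates of a mask
#'
#' @param mask binary matrix.
#' @return Two-column matrix of (row, col) coordinates of foreground pixels.
#' @export
mask_points <- function(mask) {
  which(mask != 0, arr.ind = TRUE)
}

#' Hausdorff distance between two binary masks, in pixel units
#'
#' Computed on the foreground pixel coordinate sets (interior pixels never
#' realize the max-min, so this equals the boundary-based distance).
#' Undefined (`NA`) when either mask is empty.
#'
#' @param pred,gt binary masks of identical dimensions.
#' @return Scalar in pixels, or `NA`.
#' @export
mask_hausdorff <- function(pred, gt) {
  check_mask_pair(pred, gt)
  A <- mask_points(pred); B <- mask_points(gt)
  if (nrow(A) == 0L || nrow(B) == 0L) return(NA_real_)
  hausdorff(A, B)
}

#' Evaluate a cohort of prediction / ground-truth pairs
#'
#' Computes TPR, TNR, DSC and symmetric Hausdorff distance per pair plus
#' arithmetic means. Pairs where a metric is undefined (empty masks) are
#' excluded from that metric's mean and counted in `n_excluded`.
#'
#' @param pairs list of `list(pred = , gt = )` binary-mask pairs.
#' @return A `suvseg_metrics_report`: `per_pair` (data.frame with one row
#'   per pair), `means` (named numeric), `n_excluded` (named integer).
#' @export
evaluate_cohort <- function(pairs) {
  if (length(pairs) == 0L) {
    stop_suvseg("evaluate_cohort requires at least one pair",
                class = "suvseg_config_error")
  }
  rows <- lapply(pairs, function(p) {
    cc <- confusion_counts(p$pred, p$gt)
    data.frame(tpr = tpr(cc), tnr = tnr(cc), dsc = dsc(p$pred, p$gt),
               hd = mask_hausdorff(p$pred, p$gt))
  })
  per_pair <- do.call(rbind, rows)
  means <- vapply(per_pair, function(x) mean(x, na.rm = TRUE), 0)
  n_excl <- vapply(per_pair, function(x) sum(is.na(x)), 0L)
  if (any(n_excl > 0)) {
    message(sprintf("evaluate_cohort: excluded undefined values per metric: %s",
                    paste(names(n_excl), n_excl, sep = "=", collapse = ", ")))
  }
  structure(list(per_pair = per_pair, means = means, n_excluded = n_excl),
            class = "suvseg_metrics_report")
}

#' @export
print.suvseg_metrics_report <- function(x, ...) {
  cat(sprintf("<suvseg_metrics_report> %d pairs\n", nrow(x$per_pair)))
  cat(sprintf("  mean TPR %.4f  TNR %.4f  DSC %.4f  HD %.2f px\n",
              x$means["tpr"], x$means["tnr"], x$means["dsc"], x$means["hd"]))
  if (any(x$n_excluded > 0)) {
    cat("  excluded (undefined):",
        paste(names(x$n_excluded), x$n_excluded, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
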