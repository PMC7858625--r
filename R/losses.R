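#' Tversky loss parameters
#'
#' The Tversky index generalizes Dice with separate penalties on the two
#' error types. Following the convention used throughout this package,
#' `alpha` weights false negatives and `beta` weights false positives; the
#' defaults (0.7 / 0.3) penalize under-segmentation more than
#' over-segmentation, which counteracts the extreme foreground/background
#' class imbalance of small structures such as the labyrinth. (Note that
#' some references attach the symbols the other way around.)
#'
#' @param alpha False-negative penalty weight (>= 0), default 0.7.
#' @param beta False-positive penalty weight (>= 0), default 0.3.
#' @param epsilon Smoothing constant (>= 0) applied to numerator and
#'   denominator; the default 1e-6 guards empty-foreground volumes (0 gives
#'   the unsmoothed index, undefined when both masks are empty).
#' @return A list of class `tversky_params`.
#' @export
tversky_params <- function(alpha = 0.7, beta = 0.3, epsilon = 1e-6) {
  if (alpha < 0 || beta < 0) abort("alpha and beta must be >= 0")
  if (epsilon < 0) abort("epsilon must be >= 0")
  structure(list(alpha = alpha, beta = beta, epsilon = epsilon),
            class = "tversky_params")
}

check_pred_gt <- function(pred, gt) {
  p <- as.vector(if (inherits(pred, "volume_image")) pred$voxels else pred)
  g <- as.vector(if (inherits(gt, "volume_image")) gt$voxels else gt)
  if (length(p) != length(g)) {
    abort("prediction and ground truth must have the same shape",
          class = "otoseg_shape_error")
  }
  if (any(p < 0 | p > 1)) {
    abort("predicted probabilities must lie in [0, 1]",
          class = "otoseg_validation_error")
  }
  list(p = p, g = g)
}

#' Tversky loss on soft predictions
#'
#' `1 - TI` with
#' `TI = (sum(p*g) + eps) / (sum(p*g) + alpha*sum((1-p)*g) + beta*sum(p*(1-g)) + eps)`.
#' With `alpha = beta = 0.5` this reduces to the soft-Dice loss.
#'
#' @param pred Probability field in \[0, 1\] (array or [volume_image()]).
#' @param gt Binary ground-truth field of the same shape.
#' @param params A [tversky_params()].
#' @return Scalar loss in \[0, 1\]; 0 for a perfect hard prediction.
#' @export
tversky_loss <- function(pred, gt, params = tversky_params()) {
  z <- check_pred_gt(pred, gt)
  spg <- sum(z$p * z$g)
  num <- spg + params$epsilon
  den <- spg + params$alpha * (sum(z$g) - spg) +
    params$beta * (sum(z$p) - spg) + params$epsilon
  1 - num / den
}

#' Soft-Dice loss
#'
#' `1 - (2*sum(p*g) + eps) / (sum(p) + sum(g) + eps)`; the symmetric
#' reference against which the Tversky loss at `alpha = beta = 0.5` is an
#' algebraic identity, and the monitoring quantity `1 - DSC` on hard masks.
#'
#' @inheritParams tversky_loss
#' @param epsilon Smoothing constant (> 0).
#' @return Scalar loss in \[0, 1\].
#' @export
soft_dice_loss <- function(pred, gt, epsilon = 1e-6) {
  z <- check_pred_gt(pred, gt)
  1 - (2 * sum(z$p * z$g) + epsilon) / (sum(z$p) + sum(z$g) + epsilon)
}
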