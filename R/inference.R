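#' Threshold a probability field into a hard mask
#'
#' Uses the `>=` rule: a probability exactly equal to `threshold` is
#' foreground.
#'
#' @param probs Numeric array of probabilities in \[0, 1\].
#' @param threshold Decision threshold in (0, 1).
#' @return Numeric \{0, 1\} array of the same shape.
#' @export
threshold_probabilities <- function(probs, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    abort("`threshold` must be a single number strictly inside (0, 1)",
          class = "otoseg_validation_error")
  }
  array(as.numeric(probs >= threshold), dim(probs))
}

#' End-to-end prediction on a raw volume
#'
#' Preprocess (resample to isotropic spacing, min-max rescale, center
#' crop/pad), run the network, threshold the probability field, and restore
#' the mask. Thresholding uses the `>=` rule, so a probability of exactly
#' `threshold` is foreground. Two masks are returned: the evaluation-space
#' mask on the isotropic grid (crop/pad inverted only — the space in which
#' metrics are computed) and the mask resampled back to the original grid.
#'
#' @param object A trained `otoseg_model`.
#' @param vol A raw [volume_image()].
#' @param pre_cfg A [preprocess_config()]; its `crop_shape` must equal the
#'   model input shape.
#' @param threshold Decision threshold in (0, 1), default 0.5.
#' @param ... Unused.
#' @return List of class `otoseg_prediction` with `eval_mask`
#'   ([binary_mask()] on the isotropic grid), `original_mask`
#'   ([binary_mask()] on the input grid), `probabilities` (3D array on the
#'   crop grid) and `record` (the `crop_record`).
#' @export
predict.otoseg_model <- function(object, vol, pre_cfg = preprocess_config(),
                                 threshold = 0.5, ...) {
  if (!all(pre_cfg$crop_shape == object$config$input_shape)) {
    abort("preprocessing crop_shape must equal the model input shape",
          class = "otoseg_config_error")
  }
  pre <- preprocess_volume(vol, pre_cfg)
  probs <- forward_pass(object, pre$volume)
  hard <- threshold_probabilities(probs, threshold)
  crop_mask <- binary_mask(hard, pre$volume$spacing, pre$volume$affine)
  eval_mask <- invert_crop_pad(crop_mask, pre$record)
  orig_mask <- restore_to_original(crop_mask, pre$record)
  structure(list(eval_mask = eval_mask, original_mask = orig_mask,
                 probabilities = probs, record = pre$record),
            class = "otoseg_prediction")
}

#' @export
print.otoseg_prediction <- function(x, ...) {
  cat(sprintf(
    "<otoseg_prediction> eval-space volume %.2f mm^3, original-grid volume %.2f mm^3\n",
    mask_volume_mm3(x$eval_mask), mask_volume_mm3(x$original_mask)))
  invisible(x)
}
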