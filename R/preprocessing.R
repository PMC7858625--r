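#' Preprocessing configuration
#'
#' The three preprocessing steps applied before a volume enters the model:
#' isotropic cubic B-spline resampling, min-max intensity rescaling to
#' \[0, 1\], and a fixed-size center crop with zero padding. Defaults match
#' the production pipeline: 0.45 mm isotropic voxels and a 256 x 256 x 64
#' crop, large enough to retain context around both inner ears.
#'
#' @param target_spacing Isotropic target voxel size in mm (> 0).
#' @param crop_shape Integer length-3 output shape in voxels (all >= 1).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(target_spacing = 0.45,
                              crop_shape = c(256L, 256L, 64L)) {
  if (!is.numeric(target_spacing) || length(target_spacing) != 1L ||
      !is.finite(target_spacing) || target_spacing <= 0) {
    abort("`target_spacing` must be a single positive number (mm)")
  }
  crop_shape <- as.integer(crop_shape)
  if (length(crop_shape) != 3L || any(crop_shape < 1L)) {
    abort("`crop_shape` must be 3 integers >= 1")
  }
  structure(list(target_spacing = target_spacing, crop_shape = crop_shape,
                 intensity_range = c(0, 1)),
            class = "preprocess_config")
}

#' Resample a volume or mask to isotropic spacing
#'
#' Images are interpolated with a cubic B-spline (with the exact
#' interpolation prefilter, so the interpolant passes through the original
#' samples and reproduces constants); masks use nearest-neighbour and stay
#' binary. The output grid has shape `round(shape * spacing / target)` and
#' voxel centres aligned at index 0.
#'
#' @param vol A [volume_image()] or [binary_mask()].
#' @param cfg A [preprocess_config()].
#' @param kind `"image"` or `"mask"`; defaults to the class of `vol`.
#' @return Resampled object of the same class as `vol`.
#' @export
resample_isotropic <- function(vol, cfg = preprocess_config(),
                               kind = c("auto", "image", "mask")) {
  kind <- match.arg(kind)
  if (kind == "auto") kind <- if (inherits(vol, "binary_mask")) "mask" else "image"
  in_dims <- dim(vol$voxels)
  if (any(in_dims < 1L)) {
    abort("degenerate axis: every axis must have extent >= 1",
          class = "otoseg_validation_error")
  }
  target <- rep(cfg$target_spacing, 3)
  out_dims <- as.integer(round(in_dims * vol$spacing / target))
  out_dims <- pmax(out_dims, 1L)
  method <- if (kind == "mask") "nearest" else "bspline"
  arr <- .resample_grid(vol$voxels, as.integer(in_dims), vol$spacing,
                        out_dims, target, method)
  # affine: new index i corresponds to old continuous index i * target/spacing
  scale <- diag(c(target / vol$spacing, 1))
  affine <- vol$affine %*% scale
  if (kind == "mask") {
    binary_mask(arr, target, affine)
  } else {
    volume_image(arr, target, affine)
  }
}

#' Min-max rescale intensities to \[0, 1\]
#'
#' `v -> (v - min) / (max - min)` using the per-volume extremes. A constant
#' volume cannot be rescaled; it is mapped to all zeros with a warning.
#'
#' @param vol A [volume_image()].
#' @return A [volume_image()] with minimum 0 and maximum 1 (or all zeros).
#' @export
rescale_intensity <- function(vol) {
  v <- vol$voxels
  if (!all(is.finite(v))) {
    abort("intensities must be finite", class = "otoseg_validation_error")
  }
  lo <- min(v); hi <- max(v)
  if (hi == lo) {
    warn("constant-intensity volume: rescaled output is all zeros")
    out <- array(0, dim(v))
  } else {
    out <- (v - lo) / (hi - lo)
  }
  volume_image(out, vol$spacing, vol$affine)
}

crop_pad_offsets <- function(in_shape, crop_shape) {
  # positive = crop offset (low side), negative = pad amount (low side);
  # odd remainders put the extra voxel on the high-index side
  as.integer(floor((in_shape - crop_shape) / 2))
}

#' Center crop or zero-pad to a fixed shape
#'
#' Axes larger than `crop_shape` are cropped to a centered window; smaller
#' axes are symmetrically zero-padded. Odd remainders place the extra voxel
#' on the high-index side in both directions. Returns the cropped volume
#' together with an invertible `crop_record` for restoring predictions.
#'
#' @param vol A [volume_image()] or [binary_mask()], already resampled.
#' @param cfg A [preprocess_config()].
#' @param original Optional original (pre-resampling) [volume_image()] whose
#'   shape/spacing/affine are stored in the record; defaults to `vol` itself
#'   (i.e. no resampling happened).
#' @return List with elements `volume` (shape `cfg$crop_shape`) and `record`
#'   (class `crop_record` with fields `original_shape`, `original_spacing`,
#'   `original_affine`, `resampled_shape`, `resampled_spacing`,
#'   `crop_offsets`).
#' @export
center_crop_pad <- function(vol, cfg = preprocess_config(), original = NULL) {
  in_shape <- dim(vol$voxels)
  crop <- cfg$crop_shape
  off <- crop_pad_offsets(in_shape, crop)
  out <- array(0, crop)
  src_lo <- pmax(off, 0L) + 1L
  src_hi <- pmin(off + crop, in_shape)
  dst_lo <- pmax(-off, 0L) + 1L
  dst_hi <- dst_lo + (src_hi - src_lo)
  out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
    vol$voxels[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
  ref <- original %||% vol
  record <- structure(
    list(original_shape = as.integer(dim(ref$voxels)),
         original_spacing = ref$spacing,
         original_affine = ref$affine,
         resampled_shape = as.integer(in_shape),
         resampled_spacing = vol$spacing,
         crop_offsets = off),
    class = "crop_record")
  cropped <- if (inherits(vol, "binary_mask")) {
    binary_mask(out, vol$spacing, vol$affine)
  } else {
    volume_image(out, vol$spacing, vol$affine)
  }
  list(volume = cropped, record = record)
}

#' Invert the crop/pad step only
#'
#' Places a crop-grid mask back onto the resampled (isotropic) grid recorded
#' in `rec`; voxels outside the crop window are 0. This is the evaluation
#' space: metrics are computed here, on a common isotropic grid.
#'
#' @param mask A [binary_mask()] on the crop grid.
#' @param rec A `crop_record` from [center_crop_pad()].
#' @return A [binary_mask()] with shape `rec$resampled_shape`.
#' @export
invert_crop_pad <- function(mask, rec) {
  crop <- dim(mask$voxels)
  expected <- rec$resampled_shape
  off <- rec$crop_offsets
  if (!all(crop_pad_offsets(expected, crop) == off)) {
    abort("mask shape does not match the crop record",
          class = "otoseg_validation_error")
  }
  out <- array(0, expected)
  src_lo <- pmax(-off, 0L) + 1L
  src_hi <- pmin(crop, expected - off)
  dst_lo <- pmax(off, 0L) + 1L
  dst_hi <- dst_lo + (src_hi - src_lo)
  out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
    mask$voxels[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
  scale <- diag(c(rec$resampled_spacing / rec$original_spacing, 1))
  binary_mask(out, rec$resampled_spacing, rec$original_affine %*% scale)
}

#' Restore a crop-grid mask to the original grid
#'
#' Inverse crop/pad followed by nearest-neighbour resampling back to the
#' original shape and spacing stored in the record.
#'
#' @inheritParams invert_crop_pad
#' @return A [binary_mask()] with the original shape, spacing and affine.
#' @export
restore_to_original <- function(mask, rec) {
  iso <- invert_crop_pad(mask, rec)
  arr <- .resample_grid(iso$voxels, rec$resampled_shape, rec$resampled_spacing,
                        rec$original_shape, rec$original_spacing, "nearest")
  binary_mask(arr, rec$original_spacing, rec$original_affine)
}

#' Full preprocessing: resample, rescale, crop
#'
#' Rescaling happens before cropping so that padding zeros cannot perturb
#' the per-volume minimum.
#'
#' @param vol A raw [volume_image()].
#' @param cfg A [preprocess_config()].
#' @return List with `volume` (preprocessed, shape `cfg$crop_shape`,
#'   intensities in \[0, 1\]) and `record` (a `crop_record`).
#' @export
preprocess_volume <- function(vol, cfg = preprocess_config()) {
  iso <- resample_isotropic(vol, cfg, kind = "image")
  iso <- rescale_intensity(iso)
  center_crop_pad(iso, cfg, original = vol)
}

#' Preprocess a ground-truth mask into evaluation space
#'
#' Resamples a mask to the isotropic evaluation grid (nearest-neighbour).
#' Use this to compare ground truth with predictions on a common grid.
#'
#' @param mask A [binary_mask()] on the original grid.
#' @param cfg A [preprocess_config()].
#' @return A [binary_mask()] on the isotropic grid.
#' @export
mask_to_eval_space <- function(mask, cfg = preprocess_config()) {
  resample_isotropic(mask, cfg, kind = "mask")
}

#' Serialize / read a crop record as JSON
#' @param rec A `crop_record`.
#' @param path JSON file path.
#' @return `write_crop_record` returns `path` invisibly; `read_crop_record`
#'   returns a `crop_record`.
#' @export
write_crop_record <- function(rec, path) {
  jsonlite::write_json(unclass(rec), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_crop_record
#' @export
read_crop_record <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$original_shape <- as.integer(x$original_shape)
  x$resampled_shape <- as.integer(x$resampled_shape)
  x$crop_offsets <- as.integer(x$crop_offsets)
  x$original_affine <- matrix(unlist(x$original_affine), 4, 4)
  structure(x, class = "crop_record")
}
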