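#' 3D volume with voxel spacing and affine metadata
#'
#' A `volume_image` is the unit every pipeline stage consumes and produces:
#' a 3D scalar array together with its per-axis voxel size in millimetres and
#' a 4x4 grid-index-to-world affine. Arrays are indexed (X, Y, Z) following
#' the NIfTI i, j, k convention; the slice direction is the third axis.
#'
#' @param voxels 3D numeric array.
#' @param spacing Numeric length-3, voxel size in mm per axis; all entries
#'   must be strictly positive and finite.
#' @param affine Optional 4x4 grid-to-world affine; defaults to a diagonal
#'   scaling by `spacing`. Must be invertible.
#' @return An object of class `volume_image` with fields `voxels`, `spacing`
#'   and `affine`.
#' @examples
#' vol <- volume_image(array(rnorm(8^3), c(8, 8, 8)), spacing = c(0.45, 0.45, 0.45))
#' voxel_volume(vol)
#' @export
volume_image <- function(voxels, spacing, affine = NULL) {
  if (length(dim(voxels)) != 3L) {
    abort(sprintf("`voxels` must have exactly 3 axes, got %d",
                  length(dim(voxels))), class = "otoseg_dim_error")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be 3 strictly positive finite values (mm)",
          class = "otoseg_metadata_error")
  }
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) ||
      !is.finite(d <- det(affine)) || abs(d) < .Machine$double.eps) {
    abort("`affine` must be an invertible 4x4 matrix",
          class = "otoseg_metadata_error")
  }
  structure(list(voxels = voxels, spacing = spacing, affine = affine),
            class = "volume_image")
}

#' Binary segmentation mask on a volume grid
#'
#' A `binary_mask` carries the same spacing/affine metadata as its companion
#' [volume_image()] and restricts voxel values to \{0, 1\}.
#'
#' @inheritParams volume_image
#' @return An object of class `c("binary_mask", "volume_image")`.
#' @export
binary_mask <- function(voxels, spacing, affine = NULL) {
  vals <- unique(as.vector(voxels))
  if (!all(vals %in% c(0, 1))) {
    abort("mask voxels must all be 0 or 1", class = "otoseg_validation_error")
  }
  storage.mode(voxels) <- "double"
  out <- volume_image(voxels, spacing, affine)
  class(out) <- c("binary_mask", "volume_image")
  out
}

#' @export
print.volume_image <- function(x, ...) {
  kind <- if (inherits(x, "binary_mask")) "binary_mask" else "volume_image"
  cat(sprintf("<%s> %s voxels @ %s mm\n", kind,
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = " x ")))
  if (inherits(x, "binary_mask")) {
    cat(sprintf("  foreground: %d voxels, %.2f mm^3\n",
                sum(x$voxels > 0), mask_volume_mm3(x)))
  } else {
    cat(sprintf("  intensity range: [%.4g, %.4g]\n",
                min(x$voxels), max(x$voxels)))
  }
  invisible(x)
}

#' Physical size of one voxel in cubic millimetres
#' @param vol A [volume_image()] or [binary_mask()].
#' @return Scalar, sx * sy * sz in mm^3.
#' @export
voxel_volume <- function(vol) prod(vol$spacing)

#' Foreground volume of a mask in cubic millimetres
#' @param mask A [binary_mask()].
#' @return Scalar mm^3 (foreground voxel count times voxel volume).
#' @export
mask_volume_mm3 <- function(mask) sum(mask$voxels > 0) * voxel_volume(mask)

read_nifti_checked <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "otoseg_io_error")
  }
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))  # drop niftiImage attributes
  if (length(dim(arr)) != 3L) {
    abort(sprintf("expected a 3D NIfTI image, got %dD: %s",
                  length(dim(arr)), path),
          class = "otoseg_dim_error")
  }
  spacing <- abs(as.numeric(RNifti::pixdim(img)[1:3]))
  if (!all(is.finite(spacing)) || any(spacing <= 0)) {
    abort(sprintf("non-positive voxel spacing in header of %s", path),
          class = "otoseg_metadata_error")
  }
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = dim(affine))
  list(voxels = arr, spacing = spacing, affine = affine)
}

#' Read a 3D volume from a NIfTI file
#'
#' @param path Path to a `.nii` or `.nii.gz` file containing a 3D image.
#' @return A [volume_image()] whose spacing is taken from the header
#'   `pixdim` and whose affine is the header xform.
#' @export
read_volume <- function(path) {
  parts <- read_nifti_checked(path)
  storage.mode(parts$voxels) <- "double"
  volume_image(parts$voxels, parts$spacing, parts$affine)
}

#' Write a 3D volume to a NIfTI file
#'
#' @param vol A [volume_image()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask from a NIfTI file
#'
#' Stored values are binarized with the documented threshold rule:
#' values >= 0.5 map to 1, values below to 0. A warning is raised whenever
#' any stored value is not already exactly 0 or 1.
#'
#' @param path Path to a NIfTI mask.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path) {
  parts <- read_nifti_checked(path)
  arr <- parts$voxels
  storage.mode(arr) <- "double"
  if (!all(arr %in% c(0, 1))) {
    warn(sprintf("mask %s contains non-binary values; binarizing at 0.5",
                 path))
    arr <- ifelse(arr >= 0.5, 1, 0)
    dim(arr) <- dim(parts$voxels)
  }
  binary_mask(arr, parts$spacing, parts$affine)
}

#' Write a binary mask to a NIfTI file (unsigned 8-bit)
#'
#' @param mask A [binary_mask()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  arr <- mask$voxels
  storage.mode(arr) <- "integer"
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- mask$spacing
  RNifti::qform(img) <- structure(mask$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}
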