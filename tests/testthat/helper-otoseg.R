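# Shared fixtures and independent oracles, all built in code.

# tiny network configuration used across network/training tests
tiny_cfg <- function(input_shape = c(8L, 8L, 4L)) {
  network_config(depth = 2L, base_filters = 2L, max_filters = 4L,
                 input_shape = input_shape, pyramid_scales = 2L)
}

# random binary mask on a small grid
random_mask_array <- function(dims, p = 0.3) {
  array(as.numeric(runif(prod(dims)) < p), dims)
}

# independent brute-force confusion counter: explicit voxel loop, no
# vectorized set algebra shared with the implementation
brute_force_confusion <- function(pred_arr, gt_arr) {
  tp <- 0L; fp <- 0L; fn <- 0L; tn <- 0L
  pv <- as.vector(pred_arr); gv <- as.vector(gt_arr)
  for (i in seq_along(pv)) {
    if (pv[i] > 0 && gv[i] > 0) tp <- tp + 1L
    else if (pv[i] > 0) fp <- fp + 1L
    else if (gv[i] > 0) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# ball-shaped test mask centred in a grid, radius in mm
ball_mask <- function(dims, spacing, radius_mm, center = NULL) {
  if (is.null(center)) center <- (dims - 1) / 2 * spacing
  xs <- (seq_len(dims[1]) - 1) * spacing[1]
  ys <- (seq_len(dims[2]) - 1) * spacing[2]
  zs <- (seq_len(dims[3]) - 1) * spacing[3]
  arr <- array(0, dims)
  for (k in seq_len(dims[3])) {
    d2 <- outer((xs - center[1])^2, (ys - center[2])^2, "+") +
      (zs[k] - center[3])^2
    arr[, , k] <- as.numeric(d2 <= radius_mm^2)
  }
  arr
}

# training pairs for the micro model: bright ball on noisy background
micro_pair <- function(seed, dims = c(8L, 8L, 4L)) {
  set.seed(seed)
  sp <- c(1, 1, 1)
  msk <- ball_mask(dims, sp, radius_mm = 1.6,
                   center = (dims - 1) / 2 * sp + runif(3, -0.6, 0.6))
  img <- 0.2 + 0.6 * msk + array(rnorm(prod(dims), sd = 0.08), dims)
  img <- (img - min(img)) / (max(img) - min(img))
  list(image = img, mask = msk)
}
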