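test_that("isotropic resampling obeys the shape arithmetic and preserves constants", {
  vol <- volume_image(array(7.5, c(64, 64, 64)), spacing = c(0.9, 0.9, 0.9))
  out <- resample_isotropic(vol, preprocess_config(target_spacing = 0.45))
  expect_equal(dim(out$voxels), c(128L, 128L, 128L))
  expect_equal(out$spacing, rep(0.45, 3))
  expect_lt(max(abs(out$voxels - 7.5)), 1e-6)

  aniso <- volume_image(array(rnorm(20 * 30 * 10), c(20, 30, 10)),
                        spacing = c(0.3, 0.3, 0.65))
  out2 <- resample_isotropic(aniso, preprocess_config(target_spacing = 0.45))
  expect_equal(dim(out2$voxels),
               as.integer(round(c(20, 30, 10) * c(0.3, 0.3, 0.65) / 0.45)))
})

test_that("mask resampling is nearest-neighbour, binary, and volume-preserving", {
  sp <- c(0.9, 0.9, 0.9)
  arr <- ball_mask(c(32, 32, 32), sp, radius_mm = 5)
  m <- binary_mask(arr, sp)
  before <- mask_volume_mm3(m)
  out <- resample_isotropic(m, preprocess_config(target_spacing = 0.45))
  expect_true(all(out$voxels %in% c(0, 1)))
  expect_s3_class(out, "binary_mask")
  # oracle: voxel count x spacing^3 before vs after
  after <- sum(out$voxels) * 0.45^3
  expect_lt(abs(after - before) / before, 0.05)
})

test_that("intensity rescaling maps extremes to 0 and 1 and guards constants", {
  v <- volume_image(array(c(10, 20, 30, 30, 10, 20, 10, 30), c(2, 2, 2)),
                    c(1, 1, 1))
  out <- rescale_intensity(v)
  expect_equal(sort(unique(as.vector(out$voxels))), c(0, 0.5, 1))

  already <- volume_image(array(runif(4^3), c(4, 4, 4)), c(1, 1, 1))
  already$voxels[1] <- 0; already$voxels[2] <- 1
  expect_equal(rescale_intensity(already)$voxels, already$voxels,
               tolerance = 1e-12)

  const <- volume_image(array(3, c(4, 4, 4)), c(1, 1, 1))
  expect_warning(out2 <- rescale_intensity(const), "constant")
  expect_true(all(out2$voxels == 0))
})

test_that("center crop and zero pad follow the documented offset arithmetic", {
  cfg <- preprocess_config(crop_shape = c(256L, 256L, 64L))
  big <- volume_image(array(1, c(300, 300, 80)), rep(0.45, 3))
  res <- center_crop_pad(big, cfg)
  expect_equal(dim(res$volume$voxels), c(256L, 256L, 64L))
  expect_equal(res$record$crop_offsets, c(22L, 22L, 8L))

  small <- volume_image(array(1, c(200, 200, 40)), rep(0.45, 3))
  res2 <- center_crop_pad(small, cfg)
  expect_equal(res2$record$crop_offsets, c(-28L, -28L, -12L))
  v <- res2$volume$voxels
  # symmetric zero borders: 28 voxels per side on axes 1-2, 12 on axis 3
  expect_true(all(v[1:28, , ] == 0) && all(v[229:256, , ] == 0))
  expect_true(all(v[, , 1:12] == 0) && all(v[, , 53:64] == 0))
  expect_true(all(v[29:228, 29:228, 13:52] == 1))

  # odd remainder goes to the high-index side
  odd <- volume_image(array(seq_len(5 * 4 * 4), c(5, 4, 4)), rep(1, 3))
  res3 <- center_crop_pad(odd, preprocess_config(crop_shape = c(4L, 4L, 4L)))
  expect_equal(res3$record$crop_offsets, c(0L, 0L, 0L))
  expect_equal(res3$volume$voxels, odd$voxels[1:4, , ])
})

test_that("crop then restore is the identity on the crop window", {
  set.seed(5)
  arr <- random_mask_array(c(20L, 14L, 10L))
  m <- binary_mask(arr, rep(1, 3))
  cfg <- preprocess_config(target_spacing = 1, crop_shape = c(12L, 16L, 8L))
  res <- center_crop_pad(m, cfg)
  back <- invert_crop_pad(res$volume, res$record)
  expect_equal(dim(back$voxels), dim(arr))
  # oracle: explicit index bookkeeping for crop offsets (4, -1, 1)
  off <- res$record$crop_offsets
  expect_equal(off, c(4L, -1L, 1L))
  expected <- array(0, dim(arr))
  expected[5:16, 1:14, 2:9] <- arr[5:16, 1:14, 2:9]
  expect_identical(back$voxels, expected)
})

test_that("full preprocess then restore keeps a phantom mask (DSC >= 0.95)", {
  # anisotropic acquisition so the resampling path is genuinely exercised
  ph <- generate_phantom(phantom_spec(grid_shape = c(120L, 120L, 40L),
                                      spacing = c(0.4, 0.4, 0.5),
                                      volume_range = c(250, 400)),
                         seed = 21)
  cfg <- preprocess_config(target_spacing = 0.45, crop_shape = c(96L, 96L, 48L))
  pre <- preprocess_volume(ph$image, cfg)
  iso_mask <- resample_isotropic(ph$mask, cfg, kind = "mask")
  cropped <- center_crop_pad(iso_mask, cfg, original = ph$mask)
  restored <- restore_to_original(cropped$volume, cropped$record)
  met <- compute_metrics(restored, ph$mask)
  expect_gte(met$dsc, 0.95)
  # preprocessed image contract: shape and intensity range
  expect_equal(dim(pre$volume$voxels), c(96L, 96L, 48L))
  expect_gte(min(pre$volume$voxels), 0)
  expect_lte(max(pre$volume$voxels), 1)
  expect_true(all(restored$voxels %in% c(0, 1)))
})

test_that("crop records serialize to JSON and back", {
  m <- binary_mask(random_mask_array(c(10L, 10L, 6L)), c(0.5, 0.5, 0.8))
  res <- center_crop_pad(m, preprocess_config(target_spacing = 0.5,
                                              crop_shape = c(8L, 8L, 8L)))
  f <- withr::local_tempfile(fileext = ".json")
  write_crop_record(res$record, f)
  rec <- read_crop_record(f)
  expect_equal(rec$crop_offsets, res$record$crop_offsets)
  expect_equal(rec$original_shape, res$record$original_shape)
  expect_equal(rec$original_affine, res$record$original_affine)
  back <- invert_crop_pad(res$volume, rec)
  expect_equal(dim(back$voxels), dim(m$voxels))
})
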