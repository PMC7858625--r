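test_that("default phantoms land in the target volume range and are reproducible", {
  sp <- phantom_spec()
  p1 <- generate_phantom(sp, seed = 7)
  expect_gte(p1$info$volume_mm3, 250)
  expect_lte(p1$info$volume_mm3, 550)
  # oracle: voxel count times spacing^3
  expect_equal(p1$info$volume_mm3, sum(p1$mask$voxels) * prod(sp$spacing))
  p2 <- generate_phantom(sp, seed = 7)
  expect_identical(p1$image$voxels, p2$image$voxels)
  expect_identical(p1$mask$voxels, p2$mask$voxels)
  expect_false(identical(p1$mask$voxels,
                         generate_phantom(sp, seed = 8)$mask$voxels))
})

test_that("foreground is a small bright bilateral structure", {
  p <- generate_phantom(phantom_spec(), seed = 3)
  frac <- mean(p$mask$voxels)
  expect_lt(frac, 0.01)  # class imbalance motivating the Tversky weights
  img <- p$image$voxels; msk <- p$mask$voxels > 0
  bg_sd <- sd(img[!msk])
  contrast <- mean(img[msk]) - mean(img[!msk])
  expect_gte(contrast, 3 * bg_sd)
  # bilateral: both x-halves contain foreground
  nx <- dim(msk)[1]
  expect_gt(sum(msk[1:(nx / 2), , ]), 0)
  expect_gt(sum(msk[(nx / 2 + 1):nx, , ]), 0)
})

test_that("pathology drops components from mask and signal on the affected side", {
  sp <- phantom_spec(pathology = list(side = "right", drop_canals = TRUE,
                                      drop_vestibule = TRUE))
  p <- generate_phantom(sp, seed = 5)
  intact <- generate_phantom(phantom_spec(), seed = 5)
  msk <- p$mask$voxels; nx <- dim(msk)[1]
  left <- sum(msk[1:(nx / 2), , ]); right <- sum(msk[(nx / 2 + 1):nx, , ])
  imsk <- intact$mask$voxels
  # left side untouched, right side reduced to the cochlea
  expect_identical(msk[1:(nx / 2), , ], imsk[1:(nx / 2), , ])
  expect_lt(right, 0.6 * sum(imsk[(nx / 2 + 1):nx, , ]))
  expect_gt(right, 0)
  # dropped components are dark: no bright signal off-mask on the right
  img <- p$image$voxels
  dropped <- imsk > 0 & msk == 0
  expect_gt(sum(dropped), 0)
  bg <- img[p$mask$voxels == 0 & imsk == 0]
  expect_lt(mean(img[dropped]) - mean(bg), sd(bg))
  expect_gt(p$info$intact_volume_mm3, p$info$volume_mm3)
})

test_that("cohort generation logs a manifest with the requested pathology count", {
  co <- generate_cohort(20, phantom_spec_desk(), seed = 9,
                        pathology_fraction = 0.4)
  expect_equal(nrow(co$manifest), 20)
  expect_equal(sum(co$manifest$pathology), 8)
  # manifest volumes match a recount from the masks, and intact volumes
  # stay inside the spec range
  vv <- prod(co$cases[[1]]$mask$spacing)
  recount <- vapply(co$cases, function(cs) sum(cs$mask$voxels) * vv,
                    numeric(1))
  expect_equal(co$manifest$volume_mm3, recount)
  expect_true(all(co$manifest$intact_volume_mm3 >= 45 &
                    co$manifest$intact_volume_mm3 <= 95))
  co2 <- generate_cohort(20, phantom_spec_desk(), seed = 10,
                         pathology_fraction = 0.4)
  expect_false(identical(co$manifest$volume_mm3, co2$manifest$volume_mm3))
})

test_that("oversized anatomy relative to the grid is rejected", {
  sp <- phantom_spec(grid_shape = c(24L, 24L, 12L),
                     volume_range = c(250, 550))
  expect_error(generate_phantom(sp, 1), class = "otoseg_spec_error")
})
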