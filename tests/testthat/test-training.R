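test_that("augmentation is involutive for flips and volume-preserving for rotations", {
  pair <- micro_pair(1, dims = c(16L, 16L, 8L))
  flip_cfg <- train_config(augment_flip = TRUE, augment_rotate = FALSE,
                           augment_prob = 1)
  set.seed(1)
  a1 <- augment_pair(pair$image, pair$mask, flip_cfg)
  expect_true(a1$applied$flip)
  set.seed(1)
  a2 <- augment_pair(a1$image, a1$mask, flip_cfg)
  expect_identical(a2$image, pair$image)
  expect_identical(a2$mask, pair$mask)

  # rotation by 0 degrees is the identity (exact for the nearest mask)
  rot_cfg <- train_config(augment_flip = FALSE, augment_rotate = TRUE,
                          rotate_max_deg = 0, augment_prob = 1)
  set.seed(2)
  a3 <- augment_pair(pair$image, pair$mask, rot_cfg)
  expect_identical(a3$mask, pair$mask)

  # +/- 15 degree rotation keeps the mask binary and its volume within 10%
  ph <- generate_phantom(phantom_spec_desk(), seed = 4)
  before <- sum(ph$mask$voxels)
  rot15 <- train_config(augment_flip = FALSE, augment_rotate = TRUE,
                        rotate_max_deg = 15, augment_prob = 1)
  set.seed(3)
  for (i in 1:3) {
    a <- augment_pair(ph$image$voxels, ph$mask$voxels, rot15)
    expect_true(all(a$mask %in% c(0, 1)))
    expect_lt(abs(sum(a$mask) - before) / before, 0.10)
    expect_true(abs(a$applied$angle) <= 15)
  }
})

test_that("training is reproducible, learns, and respects early stopping", {
  pairs <- lapply(1:6, micro_pair)
  cfg <- tiny_cfg()
  mod <- build_model(cfg, seed = 5)
  tc <- train_config(learning_rate = 3e-3, batch_size = 2, max_epochs = 3,
                     patience = 10, seed = 9)
  f1 <- train_segmenter(mod, pairs[1:4], pairs[5:6], tc)
  f2 <- train_segmenter(mod, pairs[1:4], pairs[5:6], tc)
  expect_equal(as.data.frame(f1$history), as.data.frame(f2$history))
  expect_identical(f1$model$params, f2$model$params)

  # learning occurs on a longer run of this learnable micro task
  tc2 <- train_config(learning_rate = 3e-3, batch_size = 2, max_epochs = 10,
                      patience = 10, seed = 9)
  f3 <- train_segmenter(mod, pairs[1:4], pairs[5:6], tc2)
  expect_lt(f3$history$train_loss[10], f3$history$train_loss[1])

  # best-epoch property: returned weights reproduce the minimum recorded
  # validation loss
  val_again <- otoseg:::eval_validation(f3$model$params, cfg, pairs[5:6],
                                        tc2$tversky)
  expect_equal(val_again$loss, min(f3$history$val_loss), tolerance = 1e-5)
  expect_equal(attr(f3$history, "best_epoch"),
               which.min(f3$history$val_loss))

  # an engineered never-improving validation set (inverted labels) trips
  # early stopping at patience 1
  inverted <- lapply(pairs[5:6], function(p) {
    list(image = p$image, mask = 1 - p$mask)
  })
  tc3 <- train_config(learning_rate = 3e-3, batch_size = 2, max_epochs = 30,
                      patience = 1, seed = 9)
  f4 <- train_segmenter(mod, pairs[1:4], inverted, tc3)
  expect_true(attr(f4$history, "stopped_early"))
  expect_lt(nrow(f4$history), 30)
  g <- glance(f4$history)
  expect_true(g$stopped_early)

  expect_error(train_segmenter(mod, list(), pairs[5:6], tc),
               class = "otoseg_config_error")
})
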