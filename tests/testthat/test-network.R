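test_that("configuration invariants hold and bad shapes are rejected", {
  cfg <- network_config()
  expect_equal(cfg$base_filters * cfg$pool_factor^(cfg$depth - 1),
               cfg$max_filters)  # 16 -> 128 over 4 levels
  expect_error(network_config(depth = 4, input_shape = c(60, 64, 32)),
               class = "otoseg_config_error")
  expect_error(network_config(depth = 4, input_shape = c(60, 64, 32)),
               regexp = "axis 1")
})

test_that("filter schedule doubles from base and caps at max_filters", {
  cfg <- network_config(depth = 4, base_filters = 16, max_filters = 128,
                        input_shape = c(16, 16, 8))
  shapes <- otoseg:::param_shapes(cfg)
  for (l in 1:4) {
    expect_equal(shapes[[sprintf("enc%d_c2_W", l)]][2], min(16 * 2^(l - 1), 128))
  }
  # cap: depth 5 at max 128 keeps the deepest level at 128
  cfg5 <- network_config(depth = 5, base_filters = 16, max_filters = 128,
                         input_shape = c(16, 16, 16))
  expect_equal(otoseg:::param_shapes(cfg5)[["enc5_c1_W"]][2], 128L)
})

test_that("parameter count matches a hand-computed layer-by-layer sum", {
  cfg <- tiny_cfg()  # depth 2, base 2, max 4, pyramid 2, 2 blocks, att_div 2
  f1 <- 2L; f2 <- 4L
  hand <- sum(
    27 * 1 * f1 + 2 * f1,                 # pyramid block level 1 (+ IN affine)
    27 * 1 * f2 + 2 * f2,                 # pyramid block level 2
    27 * (1 + f1) * f1 + 2 * f1,          # enc1 conv1 (input + pyramid concat)
    27 * f1 * f1 + 2 * f1,                # enc1 conv2
    27 * (f1 + f2) * f2 + 2 * f2,         # enc2 conv1 (pooled + pyramid)
    27 * f2 * f2 + 2 * f2,                # enc2 conv2
    8 * f2 * f1 + f1,                     # transposed conv 2x2x2
    f1 * 1 + f1 * 1 + 1 + 1 + 1,          # attention gate (m = f1/2 = 1)
    27 * (2 * f1) * f1 + 2 * f1,          # dec1 conv1 (concat)
    27 * f1 * f1 + 2 * f1,                # dec1 conv2
    f1 * 1 + 1                            # output 1x1x1 conv
  )
  expect_equal(build_model(cfg, seed = 1)$parameter_count, hand)
})

test_that("weight initialization is seed-deterministic", {
  cfg <- tiny_cfg()
  m1 <- build_model(cfg, seed = 42)
  m2 <- build_model(cfg, seed = 42)
  m3 <- build_model(cfg, seed = 43)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params, m3$params))
  expect_equal(m1$parameter_count, m3$parameter_count)
})

test_that("forward pass is shape-equivariant, bounded, and deterministic", {
  cfg <- tiny_cfg(c(8L, 8L, 8L))
  mod <- build_model(cfg, seed = 2)
  set.seed(1)
  x <- array(runif(8 * 8 * 8), c(8, 8, 8))
  p1 <- forward_pass(mod, x)
  p2 <- forward_pass(mod, x)
  expect_identical(p1, p2)
  expect_equal(dim(p1), dim(x))
  expect_true(all(is.finite(p1)) && all(p1 > 0) && all(p1 < 1))
  # the freshly initialized model is not the constant map
  p_zero <- forward_pass(mod, array(0, c(8, 8, 8)))
  p_one <- forward_pass(mod, array(1, c(8, 8, 8)))
  expect_false(isTRUE(all.equal(p_zero, p_one)))
  expect_error(forward_pass(mod, array(0, c(8, 8, 4))),
               class = "otoseg_shape_error")
})

test_that("attention coefficients live in [0,1]; forced gates act as identity/annihilation", {
  set.seed(3)
  for (rep in 1:5) {
    skip <- array(rnorm(6 * 6 * 4 * 4), c(6, 6, 4, 4))
    gate <- array(rnorm(3 * 3 * 2 * 4), c(3, 3, 2, 4))
    w <- list(Wx = matrix(rnorm(8), 4, 2), Wg = matrix(rnorm(8), 4, 2),
              b = rnorm(2), psi = matrix(rnorm(2), 2, 1), c = rnorm(1))
    res <- attention_gate(skip, gate, w)
    expect_true(all(res$coefficients >= 0 & res$coefficients <= 1))
    expect_equal(dim(res$output), dim(skip))
  }
  skip <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  gate <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  w <- list(Wx = matrix(0, 2, 1), Wg = matrix(0, 2, 1), b = 0,
            psi = matrix(0, 1, 1), c = 0)
  expect_identical(attention_gate(skip, gate, w, force_coefficients = 1)$output,
                   skip)
  expect_true(all(attention_gate(skip, gate, w,
                                 force_coefficients = 0)$output == 0))
  expect_error(attention_gate(skip, array(0, c(3, 3, 3, 2)), w),
               class = "otoseg_config_error")
})

test_that("attention coefficients inside the network are in [0,1] for random inputs", {
  cfg <- tiny_cfg(c(8L, 8L, 8L))
  set.seed(6)
  for (s in 1:3) {
    mod <- build_model(cfg, seed = s)
    x <- array(runif(8 * 8 * 8), c(8, 8, 8))
    res <- forward_pass(mod, x, return_attention = TRUE)
    for (a in res$attention) {
      expect_true(all(a >= 0 & a <= 1))
    }
  }
})

test_that("instance normalization is invariant to positive input scaling", {
  set.seed(8)
  x <- matrix(rnorm(200 * 3), 200, 3)
  tape <- otoseg:::new_tape()
  params <- list(g = c(1.3, 0.7, 2), be = c(0.1, -0.2, 0))
  block <- function(v) {
    xn <- otoseg:::op_input(tape, v, c(10L, 10L, 2L))
    otoseg:::op_instnorm(tape, xn, otoseg:::op_param(tape, params, "g"),
                         otoseg:::op_param(tape, params, "be"))$v
  }
  y1 <- block(x)
  y2 <- block(x * 37.5)
  expect_equal(y1, y2, tolerance = 1e-4)  # equal up to the norm's epsilon
})

test_that("backpropagated gradients match finite differences on a tiny net", {
  cfg <- tiny_cfg()
  mod <- build_model(cfg, seed = 3)
  set.seed(7)
  x <- array(runif(8 * 8 * 4), c(8, 8, 4))
  gt <- array(as.numeric(runif(8 * 8 * 4) > 0.8), c(8, 8, 4))
  tv <- tversky_params()
  loss_of <- function(params) {
    g <- otoseg:::net_graph(params, cfg,
                            list(v = matrix(as.vector(x), ncol = 1),
                                 d = c(8L, 8L, 4L)))
    otoseg:::op_tversky(g$tape, g$out, as.vector(gt), tv$alpha, tv$beta,
                        tv$epsilon)$v
  }
  r <- otoseg:::sample_loss_and_grads(mod$params, cfg, x, gt, tv)
  expect_setequal(names(r$grads), names(mod$params))
  h <- 1e-3
  # directional derivative along a fixed random direction (averages away
  # single-precision kernel noise)
  dirs <- lapply(mod$params, function(p) {
    d <- array(rnorm(length(p)), if (is.matrix(p)) dim(p) else length(p))
    d / sqrt(sum(d^2))
  })
  pp <- mod$params; pm <- mod$params; dot <- 0
  for (nm in names(mod$params)) {
    pp[[nm]] <- pp[[nm]] + h * dirs[[nm]]
    pm[[nm]] <- pm[[nm]] - h * dirs[[nm]]
    dot <- dot + sum(r$grads[[nm]] * dirs[[nm]])
  }
  fd <- (loss_of(pp) - loss_of(pm)) / (2 * h)
  expect_equal(fd, dot, tolerance = 0.02)  # kernels accumulate in float32
  # per-entry spot check
  set.seed(12)
  for (nm in sample(names(mod$params), 8)) {
    ii <- sample(length(mod$params[[nm]]), 1)
    p1 <- mod$params; p1[[nm]][ii] <- p1[[nm]][ii] + h
    p2 <- mod$params; p2[[nm]][ii] <- p2[[nm]][ii] - h
    fd1 <- (loss_of(p1) - loss_of(p2)) / (2 * h)
    an <- r$grads[[nm]][ii]
    expect_lt(abs(fd1 - an) / max(1e-4, abs(fd1) + abs(an)), 0.05)
  }
})
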