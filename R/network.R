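#' Network configuration for the attention-gated 3D U-Net
#'
#' Describes the encoder/decoder topology: `depth` encoder levels with
#' 3x3x3 convolutions, instance normalization and ReLU, filter counts
#' doubling from `base_filters` up to `max_filters`, 2x max pooling between
#' levels, transposed convolutions for 2x up-sampling, attention gates on
#' every skip connection, and an input image pyramid feeding downsampled
#' copies of the input (scales 1, 1/2, 1/4, ...) into the first
#' `pyramid_scales` encoder levels. Defaults reproduce the production
#' topology: 4 levels, 16 to 128 encoder filters, 3 pyramid scales.
#'
#' @param depth Number of encoder levels (>= 2).
#' @param base_filters Filters at the first level.
#' @param max_filters Cap on filters at the deepest level; the default
#'   schedule doubles per level, `base_filters * 2^(depth-1)` at the bottom.
#' @param input_shape Voxel shape the model accepts; each axis must be
#'   divisible by `2^(depth-1)`.
#' @param pyramid_scales Number of encoder levels that receive a pyramid
#'   copy of the input (`<= depth`).
#' @param blocks_per_level Convolution blocks per level (default 2, the
#'   classical U-Net choice).
#' @param att_div Attention-gate intermediate width = skip channels / att_div
#'   (minimum 1).
#' @return A list of class `network_config`.
#' @export
network_config <- function(depth = 4L, base_filters = 16L, max_filters = 128L,
                           input_shape = c(256L, 256L, 64L),
                           pyramid_scales = 3L, blocks_per_level = 2L,
                           att_div = 2L) {
  depth <- as.integer(depth)
  if (depth < 2L) abort("`depth` must be >= 2")
  pyramid_scales <- min(as.integer(pyramid_scales), depth)
  input_shape <- as.integer(input_shape)
  div <- 2L^(depth - 1L)
  bad <- which(input_shape %% div != 0L)
  if (length(bad)) {
    abort(sprintf(
      "input_shape axis %s (= %d) not divisible by 2^(depth-1) = %d",
      paste(bad, collapse = ","), input_shape[bad[1]], div),
      class = "otoseg_config_error")
  }
  structure(list(depth = depth, base_filters = as.integer(base_filters),
                 max_filters = as.integer(max_filters),
                 kernel = c(3L, 3L, 3L), pool_factor = 2L,
                 pyramid_scales = pyramid_scales,
                 blocks_per_level = as.integer(blocks_per_level),
                 input_shape = input_shape,
                 att_div = as.integer(att_div),
                 normalization = "instance", activation = "relu",
                 attention = TRUE),
            class = "network_config")
}

level_filters <- function(cfg, l) {
  as.integer(min(cfg$base_filters * 2^(l - 1), cfg$max_filters))
}

# channel arithmetic for every parameterized layer; single source of truth
# for both initialization and the parameter count
param_shapes <- function(cfg) {
  D <- cfg$depth; P <- cfg$pyramid_scales; B <- cfg$blocks_per_level
  f <- vapply(seq_len(D), function(l) level_filters(cfg, l), integer(1))
  shapes <- list()
  # conv blocks carry no bias: the instance-norm shift makes it redundant
  conv_block <- function(prefix, cin, cout) {
    s <- list()
    s[[paste0(prefix, "_W")]] <- c(27L * cin, cout)
    s[[paste0(prefix, "_g")]] <- cout
    s[[paste0(prefix, "_be")]] <- cout
    s
  }
  for (l in seq_len(P)) {
    shapes <- c(shapes, conv_block(sprintf("pyr%d", l), 1L, f[l]))
  }
  for (l in seq_len(D)) {
    cin <- if (l == 1L) 1L + (if (P >= 1L) f[1] else 0L)
           else f[l - 1L] + (if (l <= P) f[l] else 0L)
    for (k in seq_len(B)) {
      shapes <- c(shapes, conv_block(sprintf("enc%d_c%d", l, k),
                                     if (k == 1L) cin else f[l], f[l]))
    }
  }
  for (l in seq(D - 1L, 1L)) {
    shapes[[sprintf("up%d_W", l)]] <- c(8L * f[l + 1L], f[l])
    shapes[[sprintf("up%d_b", l)]] <- f[l]
    m <- max(1L, f[l] %/% cfg$att_div)
    shapes[[sprintf("att%d_Wx", l)]] <- c(f[l], m)
    shapes[[sprintf("att%d_Wg", l)]] <- c(f[l], m)
    shapes[[sprintf("att%d_b", l)]] <- m
    shapes[[sprintf("att%d_psi", l)]] <- c(m, 1L)
    shapes[[sprintf("att%d_c", l)]] <- 1L
    for (k in seq_len(B)) {
      shapes <- c(shapes, conv_block(sprintf("dec%d_c%d", l, k),
                                     if (k == 1L) 2L * f[l] else f[l], f[l]))
    }
  }
  shapes[["out_W"]] <- c(f[1], 1L)
  shapes[["out_b"]] <- 1L
  shapes
}

he_normal <- function(shape, fan_in) {
  v <- rnorm(prod(shape), sd = sqrt(2 / fan_in))
  if (length(shape) == 2L) matrix(v, shape[1], shape[2]) else v
}

init_params <- function(cfg, seed) {
  shapes <- param_shapes(cfg)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  params <- list()
  for (name in names(shapes)) {
    sh <- shapes[[name]]
    params[[name]] <-
      if (grepl("_W$|_Wx$|_Wg$|_psi$", name)) he_normal(sh, fan_in = sh[1]) else
      if (grepl("_g$", name)) rep(1, sh) else
      rep(0, sh)  # biases and instance-norm shifts start at zero
  }
  # start the output layer at the background prior: with heavily imbalanced
  # foregrounds an initial ~0.5 probability floods the overlap-loss
  # denominator with false positives and stalls the early gradients
  params[["out_b"]] <- -4
  params
}

#' Build the attention-gated 3D U-Net
#'
#' Weights are drawn with He-normal initialization (convolution and
#' projection weights ~ N(0, 2/fan_in); biases zero; instance-norm scale 1,
#' shift 0), deterministically from `seed`. Convolutions inside normalized
#' blocks carry no bias term: instance normalization subtracts the
#' per-channel mean, so a preceding bias is exactly redundant and its shift
#' parameter takes that role. The parameter count depends only on the
#' configuration.
#'
#' @param cfg A [network_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `otoseg_model` with fields `params`, `config`
#'   and `parameter_count`.
#' @export
build_model <- function(cfg = network_config(), seed = 1L) {
  params <- init_params(cfg, seed)
  structure(list(params = params, config = cfg,
                 parameter_count = sum(vapply(params, length, numeric(1))),
                 seed = as.integer(seed)),
            class = "otoseg_model")
}

#' @export
print.otoseg_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<otoseg_model> attention 3D U-Net: depth %d, filters %d..%d, input %s\n",
    cfg$depth, cfg$base_filters, level_filters(cfg, cfg$depth),
    paste(cfg$input_shape, collapse = "x")))
  cat(sprintf("  parameters: %s (seed %d)\n",
              format(x$parameter_count, big.mark = ","), x$seed))
  invisible(x)
}

as_input_matrix <- function(vol) {
  arr <- if (inherits(vol, "volume_image")) vol$voxels else vol
  list(v = matrix(as.vector(arr), ncol = 1L), d = as.integer(dim(arr)))
}

# Build the full forward graph on a tape. Returns the tape, the output
# probability node, and the attention-coefficient nodes per decoder level.
net_graph <- function(params, cfg, x) {
  dims <- x$d
  if (!all(dims == cfg$input_shape)) {
    abort(sprintf("input shape %s does not match model input %s",
                  paste(dims, collapse = "x"),
                  paste(cfg$input_shape, collapse = "x")),
          class = "otoseg_shape_error")
  }
  D <- cfg$depth; P <- cfg$pyramid_scales; B <- cfg$blocks_per_level
  tape <- new_tape()
  pn <- function(name) op_param(tape, params, name)
  conv_block <- function(xnd, prefix) {
    y <- op_conv3(tape, xnd, pn(paste0(prefix, "_W")), NULL)
    y <- op_instnorm(tape, y, pn(paste0(prefix, "_g")), pn(paste0(prefix, "_be")))
    op_relu(tape, y)
  }
  # input image pyramid (plain values; the input needs no gradient)
  pyr_vals <- vector("list", P)
  cur <- x$v; cur_d <- dims
  for (l in seq_len(max(P, 1L))) {
    if (l <= P) pyr_vals[[l]] <- list(v = cur, d = cur_d)
    if (l < P) {
      cur <- .avgpool_fw(cur, cur_d)
      cur_d <- cur_d %/% 2L
    }
  }
  enc <- vector("list", D)
  xn <- op_input(tape, x$v, dims)
  for (l in seq_len(D)) {
    if (l > 1L) xn <- op_maxpool(tape, xn)
    if (l <= P) {
      pin <- op_input(tape, pyr_vals[[l]]$v, pyr_vals[[l]]$d)
      pb <- conv_block(pin, sprintf("pyr%d", l))
      xn <- op_concat(tape, xn, pb)
    }
    for (k in seq_len(B)) xn <- conv_block(xn, sprintf("enc%d_c%d", l, k))
    enc[[l]] <- xn
  }
  att_nodes <- vector("list", D - 1L)
  for (l in seq(D - 1L, 1L)) {
    u <- op_upconv(tape, xn, pn(sprintf("up%d_W", l)), pn(sprintf("up%d_b", l)))
    # additive attention at skip resolution: the gating signal is the
    # up-sampled decoder feature map (same grid as the skip)
    tx <- op_conv1(tape, enc[[l]], pn(sprintf("att%d_Wx", l)))
    tg <- op_conv1(tape, u, pn(sprintf("att%d_Wg", l)), pn(sprintf("att%d_b", l)))
    q <- op_relu(tape, op_add(tape, tx, tg))
    a <- op_sigmoid(tape, op_conv1(tape, q, pn(sprintf("att%d_psi", l)),
                                   pn(sprintf("att%d_c", l))))
    att_nodes[[l]] <- a
    gated <- op_attmul(tape, enc[[l]], a)
    xn <- op_concat(tape, u, gated)
    for (k in seq_len(B)) xn <- conv_block(xn, sprintf("dec%d_c%d", l, k))
  }
  out <- op_sigmoid(tape, op_conv1(tape, xn, pn("out_W"), pn("out_b")))
  list(tape = tape, out = out, attention = att_nodes)
}

#' Run the network forward on a preprocessed volume
#'
#' Deterministic in evaluation: instance normalization uses per-input
#' statistics and there are no stochastic layers.
#'
#' @param model An [build_model()] result.
#' @param vol A preprocessed [volume_image()] (intensities in \[0, 1\]) or a
#'   plain 3D array with the model's input shape.
#' @param return_attention If `TRUE`, also return the per-level attention
#'   coefficient fields.
#' @return A 3D array of voxel-wise foreground probabilities in (0, 1) with
#'   the input's shape; with `return_attention = TRUE`, a list with elements
#'   `probabilities` and `attention` (list of 3D arrays, finest level first).
#' @export
forward_pass <- function(model, vol, return_attention = FALSE) {
  x <- as_input_matrix(vol)
  g <- net_graph(model$params, model$config, x)
  probs <- array(g$out$v, x$d)
  if (!return_attention) return(probs)
  att <- lapply(seq_along(g$attention), function(l) {
    nd <- g$attention[[l]]
    array(nd$v, nd$d)
  })
  list(probabilities = probs, attention = att)
}

#' Apply one attention gate outside the network
#'
#' Additive attention in the formulation used on every skip connection:
#' `A = sigmoid(psi(relu(skip %*% Wx + gate %*% Wg + b)) + c)`, computed at
#' the skip resolution; the output is `skip * A` voxel-wise. If the gating
#' signal is at a coarser grid it is first nearest-neighbour upsampled to
#' the skip grid.
#'
#' @param skip 3D+channel array `(x, y, z, c)` (or `(x, y, z)` for one
#'   channel) of encoder features.
#' @param gating Feature array from the coarser decoder stage; spatial shape
#'   must equal the skip shape or half of it on every axis.
#' @param weights List with `Wx` (c_skip x m), `Wg` (c_gate x m), `b` (m),
#'   `psi` (m x 1), `c` (1). Channel counts must match, else a
#'   configuration error is raised.
#' @param force_coefficients Optional scalar or field substituted for the
#'   computed coefficients (diagnostic use).
#' @return List with `output` (same shape as `skip`) and `coefficients`
#'   (3D array in \[0, 1\]).
#' @export
attention_gate <- function(skip, gating, weights, force_coefficients = NULL) {
  as4d <- function(a) { if (length(dim(a)) == 3L) dim(a) <- c(dim(a), 1L); a }
  skip <- as4d(skip); gating <- as4d(gating)
  ds <- dim(skip)[1:3]; dg <- dim(gating)[1:3]
  if (!all(ds == dg)) {
    if (all(ds == 2L * dg)) {
      up <- apply(gating, 4, function(ch) {
        .resample_grid(array(ch, dg), dg, c(1, 1, 1), ds, c(0.5, 0.5, 0.5),
                       "nearest")
      })
      gating <- array(up, c(ds, dim(gating)[4]))
    } else {
      abort("gating shape must equal the skip shape or half of it",
            class = "otoseg_config_error")
    }
  }
  cs <- dim(skip)[4]; cg <- dim(gating)[4]
  if (nrow(weights$Wx) != cs || nrow(weights$Wg) != cg ||
      ncol(weights$Wx) != ncol(weights$Wg)) {
    abort("attention weight channel counts do not match the inputs",
          class = "otoseg_config_error")
  }
  n <- prod(ds)
  xs <- matrix(skip, n, cs); xg <- matrix(gating, n, cg)
  if (is.null(force_coefficients)) {
    q <- pmax(sweep(xs %*% weights$Wx + xg %*% weights$Wg, 2, weights$b, "+"), 0)
    a <- as.vector(1 / (1 + exp(-(q %*% weights$psi + weights$c))))
  } else {
    a <- rep_len(as.vector(force_coefficients), n)
  }
  out <- xs * a
  dim(out) <- dim(skip)
  if (dim(skip)[4] == 1L) dim(out) <- ds
  list(output = out, coefficients = array(a, ds))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted/initialized model: one row per parameter tensor
#' @param x An `otoseg_model`.
#' @param ... Unused.
#' @return Tibble with columns `parameter`, `shape`, `n`.
#' @export
tidy.otoseg_model <- function(x, ...) {
  tibble(parameter = names(x$params),
         shape = vapply(x$params, function(p)
           paste(if (is.matrix(p)) dim(p) else length(p), collapse = "x"),
           character(1)),
         n = vapply(x$params, length, numeric(1)))
}

#' One-row model summary
#' @param x An `otoseg_model`.
#' @param ... Unused.
#' @return Tibble with depth, filter range, input shape, parameter count.
#' @export
glance.otoseg_model <- function(x, ...) {
  cfg <- x$config
  tibble(depth = cfg$depth, base_filters = cfg$base_filters,
         max_filters = level_filters(cfg, cfg$depth),
         pyramid_scales = cfg$pyramid_scales,
         input_shape = paste(cfg$input_shape, collapse = "x"),
         parameters = x$parameter_count)
}
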