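#' Training configuration
#'
#' Adam updates at a 1e-4 initial learning rate on mini-batches of two
#' volumes, Tversky objective, per-epoch validation loss, and early stopping
#' when the validation loss stops improving. Augmentation applies, each with
#' probability `augment_prob`, a flip along the vertical in-plane axis
#' (axis 2 of the (X, Y, Z) grid) and an in-plane rotation about the slice
#' axis by a uniform angle within `rotate_max_deg`.
#'
#' @param learning_rate Adam step size (> 0), default 1e-4.
#' @param batch_size Volumes per gradient step (>= 1), default 2.
#' @param max_epochs Epoch budget.
#' @param patience Epochs without validation-loss improvement before
#'   stopping (>= 1), default 10.
#' @param augment_flip,augment_rotate Enable the two augmentations.
#' @param rotate_max_deg Maximum absolute in-plane rotation angle (degrees).
#' @param augment_prob Per-sample probability of applying each enabled
#'   augmentation.
#' @param seed Integer; weight initialization is the model's own seed, but
#'   data order and augmentation draws derive from this one.
#' @param tversky A [tversky_params()].
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 2L,
                         max_epochs = 50L, patience = 10L,
                         augment_flip = TRUE, augment_rotate = TRUE,
                         rotate_max_deg = 15, augment_prob = 0.5,
                         seed = 1L, tversky = tversky_params()) {
  if (learning_rate <= 0) abort("learning_rate must be > 0")
  if (batch_size < 1L) abort("batch_size must be >= 1")
  if (patience < 1L) abort("patience must be >= 1")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 augment_flip = isTRUE(augment_flip),
                 augment_rotate = isTRUE(augment_rotate),
                 rotate_max_deg = rotate_max_deg,
                 augment_prob = augment_prob,
                 seed = as.integer(seed), tversky = tversky),
            class = "train_config")
}

as_pair_arrays <- function(pair) {
  img <- if (inherits(pair$image, "volume_image")) pair$image$voxels else pair$image
  msk <- if (inherits(pair$mask, "volume_image")) pair$mask$voxels else pair$mask
  list(image = img, mask = msk)
}

#' Randomly augment a paired volume and mask
#'
#' The identical geometric transform is applied to both: the image is
#' interpolated linearly under rotation, the mask nearest-neighbour so it
#' stays binary. Uses the current R random number generator state.
#'
#' @param vol 3D array or [volume_image()], preprocessed.
#' @param mask Matching 3D array or [binary_mask()].
#' @param cfg A [train_config()].
#' @return List with `image`, `mask` (3D arrays) and `applied`, a list
#'   recording `flip` (logical) and `angle` (degrees, 0 when not rotated).
#' @export
augment_pair <- function(vol, mask, cfg = train_config()) {
  z <- as_pair_arrays(list(image = vol, mask = mask))
  img <- z$image; msk <- z$mask
  d <- dim(img)
  do_flip <- cfg$augment_flip && runif(1) < cfg$augment_prob
  do_rot <- cfg$augment_rotate && runif(1) < cfg$augment_prob
  angle <- if (do_rot) runif(1, -cfg$rotate_max_deg, cfg$rotate_max_deg) else 0
  if (do_flip) {
    img <- img[, d[2]:1, , drop = FALSE]
    msk <- msk[, d[2]:1, , drop = FALSE]
  }
  if (do_rot && angle != 0) {
    img <- array(.rotate_inplane(img, d, angle, "linear"), d)
    msk <- array(.rotate_inplane(msk, d, angle, "nearest"), d)
  }
  list(image = img, mask = msk, applied = list(flip = do_flip, angle = angle))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (name in names(grads)) {
    g <- grads[[name]]
    state$m[[name]] <- beta1 * state$m[[name]] + (1 - beta1) * g
    state$v[[name]] <- beta2 * state$v[[name]] + (1 - beta2) * g * g
    params[[name]] <- params[[name]] -
      lr * (state$m[[name]] / bc1) / (sqrt(state$v[[name]] / bc2) + eps)
  }
  list(params = params, state = state)
}

sample_loss_and_grads <- function(params, cfg, img_arr, msk_arr, tv) {
  x <- list(v = matrix(as.vector(img_arr), ncol = 1L),
            d = as.integer(dim(img_arr)))
  g <- net_graph(params, cfg, x)
  loss_nd <- op_tversky(g$tape, g$out, as.vector(msk_arr),
                        tv$alpha, tv$beta, tv$epsilon)
  tape_backward(g$tape, loss_nd)
  list(loss = loss_nd$v, grads = collect_param_grads(g$tape))
}

eval_validation <- function(params, cfg, val_set, tv) {
  losses <- numeric(length(val_set))
  dscs <- numeric(length(val_set))
  for (i in seq_along(val_set)) {
    z <- as_pair_arrays(val_set[[i]])
    x <- list(v = matrix(as.vector(z$image), ncol = 1L),
              d = as.integer(dim(z$image)))
    g <- net_graph(params, cfg, x)
    p <- g$out$v[, 1L]
    gt <- as.vector(z$mask)
    losses[i] <- tversky_loss(p, gt, tv)
    hard <- as.numeric(p >= 0.5)
    denom <- sum(hard) + sum(gt)
    dscs[i] <- if (denom == 0) 1 else 2 * sum(hard * gt) / denom
  }
  list(loss = mean(losses), dsc = mean(dscs))
}

#' Train the segmentation model
#'
#' Runs Adam on mini-batches (gradient = mean of per-volume Tversky
#' gradients), records training loss, validation loss and validation DSC
#' per epoch, and stops early when the validation loss has not improved for
#' `patience` epochs. The returned model carries the weights of the best
#' validation epoch. Fully reproducible given the model seed and
#' `cfg$seed`: data order and augmentation draws derive from the latter.
#'
#' @param model An [build_model()] result; its input shape must match the
#'   training volumes.
#' @param train_set,val_set Disjoint lists of pairs, each
#'   `list(image = , mask = )` of preprocessed arrays or
#'   [volume_image()]/[binary_mask()] objects, all at the model input shape.
#' @param cfg A [train_config()].
#' @param verbose Print one line per epoch.
#' @return List with `model` (best-epoch weights) and `history`, a tibble of
#'   class `otoseg_history` with columns `epoch`, `train_loss`, `val_loss`,
#'   `val_dsc` and attributes `best_epoch` and `stopped_early`.
#' @export
train_segmenter <- function(model, train_set, val_set, cfg = train_config(),
                            verbose = FALSE) {
  if (length(train_set) == 0L || length(val_set) == 0L) {
    abort("train_set and val_set must both be non-empty",
          class = "otoseg_config_error")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)
  params <- model$params
  netcfg <- model$config
  tv <- cfg$tversky
  state <- adam_init(params)
  n <- length(train_set)
  best_loss <- Inf; best_params <- params; best_epoch <- 0L
  stall <- 0L; stopped_early <- FALSE
  hist <- vector("list", cfg$max_epochs)
  for (epoch in seq_len(cfg$max_epochs)) {
    order <- sample.int(n)
    step_losses <- c()
    for (b0 in seq(1, n, by = cfg$batch_size)) {
      idx <- order[b0:min(n, b0 + cfg$batch_size - 1L)]
      acc <- NULL; bl <- 0
      for (i in idx) {
        z <- as_pair_arrays(train_set[[i]])
        aug <- augment_pair(z$image, z$mask, cfg)
        r <- sample_loss_and_grads(params, netcfg, aug$image, aug$mask, tv)
        bl <- bl + r$loss / length(idx)
        if (is.null(acc)) {
          acc <- lapply(r$grads, function(g) g / length(idx))
        } else {
          for (nm in names(r$grads)) {
            acc[[nm]] <- acc[[nm]] + r$grads[[nm]] / length(idx)
          }
        }
      }
      upd <- adam_step(params, acc, state, cfg$learning_rate)
      params <- upd$params; state <- upd$state
      step_losses <- c(step_losses, bl)
    }
    val <- eval_validation(params, netcfg, val_set, tv)
    hist[[epoch]] <- tibble(epoch = epoch, train_loss = mean(step_losses),
                            val_loss = val$loss, val_dsc = val$dsc)
    if (verbose) {
      cat(sprintf("epoch %3d  train %.4f  val %.4f  val DSC %.4f\n",
                  epoch, mean(step_losses), val$loss, val$dsc))
    }
    if (val$loss < best_loss - 1e-12) {
      best_loss <- val$loss; best_params <- params; best_epoch <- epoch
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$patience) { stopped_early <- TRUE; break }
    }
  }
  history <- dplyr::bind_rows(hist[!vapply(hist, is.null, logical(1))])
  attr(history, "best_epoch") <- best_epoch
  attr(history, "stopped_early") <- stopped_early
  class(history) <- c("otoseg_history", class(history))
  out_model <- model
  out_model$params <- best_params
  list(model = out_model, history = history)
}

#' One-row training summary
#' @param x An `otoseg_history`.
#' @param ... Unused.
#' @return Tibble with epochs run, best epoch, best validation loss/DSC,
#'   and whether early stopping triggered.
#' @export
glance.otoseg_history <- function(x, ...) {
  be <- attr(x, "best_epoch")
  tibble(epochs = nrow(x), best_epoch = be,
         best_val_loss = if (be >= 1) x$val_loss[be] else NA_real_,
         best_val_dsc = if (be >= 1) x$val_dsc[be] else NA_real_,
         stopped_early = attr(x, "stopped_early"))
}

#' Plot training and validation loss curves
#' @param object An `otoseg_history`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.otoseg_history <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object)[, c("epoch", "train_loss", "val_loss")],
    c("train_loss", "val_loss"), names_to = "series", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "best_epoch"),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "epoch", y = "Tversky loss", colour = NULL) +
    ggplot2::theme_minimal()
}
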