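# Minimal reverse-mode tape for the segmentation network. Feature maps are
# (nx*ny*nz) x C matrices (voxels column-major, x fastest); every op appends
# a node holding its value and a closure that routes the upstream gradient
# to its parents. Heavy kernels (3x3x3 conv, pooling, transposed conv) live
# in src/; the rest is vectorized R.

new_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

new_node <- function(tape, v, d, backward = NULL, param = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$v <- v
  nd$d <- d
  nd$backward <- backward
  nd$grad <- NULL
  nd$param <- param
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    length(tape$nodes) <- 2L * length(tape$nodes)
  }
  tape$nodes[[tape$n]] <- nd
  nd
}

acc_grad <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

op_input <- function(tape, v, d) new_node(tape, v, d)

op_param <- function(tape, params, name) {
  new_node(tape, params[[name]], d = NULL, param = name)
}

op_conv3 <- function(tape, x, w, b = NULL) {
  bv <- if (is.null(b)) numeric(ncol(w$v)) else b$v
  v <- .conv3d_fw(x$v, x$d, w$v, bv)
  nd <- new_node(tape, v, x$d)
  nd$backward <- function(g) {
    bw <- .conv3d_bw(x$v, x$d, w$v, g)
    acc_grad(x, bw$gx); acc_grad(w, bw$gw)
    if (!is.null(b)) acc_grad(b, bw$gb)
  }
  nd
}

# 1x1x1 convolution: plain GEMM over channels
op_conv1 <- function(tape, x, w, b = NULL) {
  v <- x$v %*% w$v
  if (!is.null(b)) v <- col_shift(v, b$v)
  nd <- new_node(tape, v, x$d)
  nd$backward <- function(g) {
    acc_grad(x, g %*% t(w$v))
    acc_grad(w, crossprod(x$v, g))
    if (!is.null(b)) acc_grad(b, colSums(g))
  }
  nd
}

# column-wise broadcast helpers (avoid sweep's aperm copies)
col_scale <- function(x, v) x * rep(v, each = nrow(x))
col_shift <- function(x, v) x + rep(v, each = nrow(x))

op_instnorm <- function(tape, x, gam, bet, eps = 1e-5) {
  n <- nrow(x$v)
  mu <- colMeans(x$v)
  xc <- col_shift(x$v, -mu)
  v2 <- colMeans(xc * xc)
  inv_sd <- 1 / sqrt(v2 + eps)
  xhat <- col_scale(xc, inv_sd)
  v <- col_shift(col_scale(xhat, gam$v), bet$v)
  nd <- new_node(tape, v, x$d)
  nd$backward <- function(g) {
    gxh <- col_scale(g, gam$v)
    s1 <- colMeans(gxh)
    s2 <- colMeans(gxh * xhat)
    gx <- col_scale(col_shift(gxh, -s1) - col_scale(xhat, s2), inv_sd)
    acc_grad(x, gx)
    acc_grad(gam, colSums(g * xhat))
    acc_grad(bet, colSums(g))
  }
  nd
}

op_relu <- function(tape, x) {
  v <- pmax(x$v, 0)
  nd <- new_node(tape, v, x$d)
  nd$backward <- function(g) acc_grad(x, g * (x$v > 0))
  nd
}

op_sigmoid <- function(tape, x) {
  v <- 1 / (1 + exp(-x$v))
  nd <- new_node(tape, v, x$d)
  nd$backward <- function(g) acc_grad(x, g * v * (1 - v))
  nd
}

op_add <- function(tape, a, b) {
  nd <- new_node(tape, a$v + b$v, a$d)
  nd$backward <- function(g) { acc_grad(a, g); acc_grad(b, g) }
  nd
}

op_concat <- function(tape, a, b) {
  ca <- ncol(a$v)
  nd <- new_node(tape, cbind(a$v, b$v), a$d)
  nd$backward <- function(g) {
    acc_grad(a, g[, seq_len(ca), drop = FALSE])
    acc_grad(b, g[, -seq_len(ca), drop = FALSE])
  }
  nd
}

# multiply every channel of x by the single-channel coefficient field a
op_attmul <- function(tape, x, a) {
  av <- a$v[, 1L]
  nd <- new_node(tape, x$v * av, x$d)
  nd$backward <- function(g) {
    acc_grad(x, g * av)
    acc_grad(a, matrix(rowSums(g * x$v), ncol = 1L))
  }
  nd
}

op_maxpool <- function(tape, x) {
  fw <- .maxpool_fw(x$v, x$d)
  n_in <- nrow(x$v)
  nd <- new_node(tape, fw$y, x$d %/% 2L)
  nd$backward <- function(g) acc_grad(x, .maxpool_bw(fw$idx, g, n_in))
  nd
}

op_upconv <- function(tape, x, w, b) {
  v <- .upconv_fw(x$v, x$d, w$v, b$v)
  nd <- new_node(tape, v, x$d * 2L)
  nd$backward <- function(g) {
    bw <- .upconv_bw(x$v, x$d, w$v, g)
    acc_grad(x, bw$gx); acc_grad(w, bw$gw); acc_grad(b, bw$gb)
  }
  nd
}

# Tversky loss node on a single-channel probability field.
op_tversky <- function(tape, p, gt, alpha, beta, eps) {
  pv <- p$v[, 1L]
  spg <- sum(pv * gt)
  sg <- sum(gt)
  sp <- sum(pv)
  num <- spg + eps
  den <- spg + alpha * (sg - spg) + beta * (sp - spg) + eps
  nd <- new_node(tape, 1 - num / den, NULL)
  nd$backward <- function(g) {
    dnum <- gt
    dden <- gt + alpha * (-gt) + beta * (1 - gt)
    dti <- (dnum * den - num * dden) / (den * den)
    acc_grad(p, matrix(-g * dti, ncol = 1L))
  }
  nd
}

tape_backward <- function(tape, loss_node) {
  loss_node$grad <- 1
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

collect_param_grads <- function(tape) {
  out <- list()
  for (i in seq_len(tape$n)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$param) && !is.null(nd$grad)) {
      out[[nd$param]] <- if (is.null(out[[nd$param]])) nd$grad else
        out[[nd$param]] + nd$grad
    }
  }
  out
}
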