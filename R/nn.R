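# Minimal define-by-run automatic differentiation for the segmentation
# network. Feature maps are dense double arrays with dims (H, W, C, N); the
# convolution and batch-norm kernels live in src/kernels.cpp. A forward pass
# records operations on a tape; backprop walks the tape in reverse.

ag_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- list()
  t$n <- 0L
  t
}

ag_node <- function(tape, value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  tape$n <- tape$n + 1L
  tape$nodes[[tape$n]] <- nd
  nd
}

ag_input <- function(tape, value) ag_node(tape, value)

# Parameters persist across passes; each forward wraps them in a fresh node.
ag_param <- function(value, name = "") {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  p$m <- NULL   # Adam first moment
  p$v <- NULL   # Adam second moment
  p$name <- name
  p
}

ag_conv <- function(tape, x, w, b, stride = 1L, pad = 1L) {
  out <- conv2d_fwd_cpp(x$value, w$value, b$value, as.integer(stride), as.integer(pad))
  ag_node(tape, out, list(x, w, b), function(dy) {
    g <- conv2d_bwd_cpp(x$value, w$value, dy, as.integer(stride), as.integer(pad))
    list(g$dx, g$dw, g$db)
  })
}

# Batch normalization. In training mode batch statistics are used and the
# running estimates in `state` (an environment with $mean, $var) are updated
# with momentum; in inference mode the running estimates are applied.
ag_bn <- function(tape, x, gamma, beta, state, training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    f <- bn_fwd_cpp(x$value, gamma$value, beta$value, eps)
    state$mean <- (1 - momentum) * state$mean + momentum * f$mean
    state$var  <- (1 - momentum) * state$var  + momentum * f$var
    ag_node(tape, f$y, list(x, gamma, beta), function(dy) {
      g <- bn_bwd_cpp(x$value, dy, gamma$value, f$mean, f$var, eps)
      list(g$dx, g$dgamma, g$dbeta)
    })
  } else {
    y <- bn_infer_cpp(x$value, gamma$value, beta$value, state$mean, state$var, eps)
    ag_node(tape, y, list(x))
  }
}

ag_relu <- function(tape, x) {
  ag_node(tape, relu_fwd_cpp(x$value), list(x), function(dy) {
    list(relu_bwd_cpp(x$value, dy))
  })
}

ag_add <- function(tape, ...) {
  xs <- list(...)
  v <- xs[[1L]]$value
  for (i in seq_along(xs)[-1L]) v <- v + xs[[i]]$value
  ag_node(tape, v, xs, function(dy) rep(list(dy), length(xs)))
}

# Nearest-neighbour 2x upsampling.
ag_upsample2 <- function(tape, x) {
  ag_node(tape, up2_fwd_cpp(x$value), list(x), function(dy) {
    list(up2_bwd_cpp(dy))
  })
}

ag_maxpool2 <- function(tape, x) {
  f <- maxpool2_fwd_cpp(x$value)
  xd <- dim(x$value)
  ag_node(tape, f$y, list(x), function(dy) {
    list(maxpool2_bwd_cpp(dy, f$argmax, as.integer(xd)))
  })
}

# Channel concatenation (dim 3).
ag_concat <- function(tape, x, y) {
  dx <- dim(x$value); dyd <- dim(y$value)
  v <- array(0, c(dx[1L], dx[2L], dx[3L] + dyd[3L], dx[4L]))
  v[, , seq_len(dx[3L]), ] <- x$value
  v[, , dx[3L] + seq_len(dyd[3L]), ] <- y$value
  ag_node(tape, v, list(x, y), function(dg) {
    list(dg[, , seq_len(dx[3L]), , drop = FALSE],
         dg[, , dx[3L] + seq_len(dyd[3L]), , drop = FALSE])
  })
}

ag_sigmoid <- function(tape, x) {
  # keep strictly inside (0, 1): extreme logits would otherwise round to 0/1
  v <- pmin(pmax(1 / (1 + exp(-x$value)), 1e-12), 1 - 1e-12)
  ag_node(tape, v, list(x), function(dy) list(dy * v * (1 - v)))
}

# Reverse-mode sweep. `seed` is dL/d(node value) for `node`.
ag_backward <- function(tape, node, seed) {
  node$grad <- seed
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backward)) next
    gs <- nd$backward(nd$grad)
    for (j in seq_along(nd$parents)) {
      p <- nd$parents[[j]]
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
    nd$grad <- NULL  # free as we go
  }
  invisible(NULL)
}

# One Adam update over a flat list of parameter environments.
adam_step <- function(params, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (p in params) {
    if (is.null(p$grad)) next
    if (is.null(p$m)) {
      p$m <- p$grad * 0
      p$v <- p$grad * 0
    }
    p$m <- beta1 * p$m + (1 - beta1) * p$grad
    p$v <- beta2 * p$v + (1 - beta2) * p$grad^2
    mhat <- p$m / (1 - beta1^t)
    vhat <- p$v / (1 - beta2^t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
    p$grad <- NULL
  }
  invisible(NULL)
}

# Combined binary cross-entropy + soft Dice loss on sigmoid probabilities.
# BCE is averaged over all pixels; the Dice term is computed per sample and
# averaged over the batch, which keeps the gradient signal strong for small
# lesions in a mostly-background slice. Returns the scalar loss and the
# gradient with respect to the pre-sigmoid logits (stable: dBCE/dz = p - t).
seg_loss <- function(prob, target, type = c("bce_plus_dice", "binary_cross_entropy", "dice")) {
  type <- match.arg(type)
  eps <- 1e-7
  p <- pmin(pmax(prob, eps), 1 - eps)
  m <- length(p)
  bce <- -mean(target * log(p) + (1 - target) * log(1 - p))
  dbce_dz <- (prob - target) / m
  d <- dim(prob)
  n <- d[4L]; plane <- d[1L] * d[2L] * d[3L]
  pm <- matrix(prob, plane, n); tm <- matrix(target, plane, n)
  sp <- colSums(pm); st <- colSums(tm); spt <- colSums(pm * tm)
  den <- sp + st + 1
  dice <- mean(1 - (2 * spt + 1) / den)
  # per-sample d(dice)/dp, then chain through sigmoid: dp/dz = p(1-p)
  ddice_dp <- -(2 * tm * rep(den, each = plane) -
                  rep(2 * spt + 1, each = plane)) / rep(den^2, each = plane) / n
  ddice_dz <- array(ddice_dp, d) * prob * (1 - prob)
  switch(type,
    binary_cross_entropy = list(loss = bce, dlogit = dbce_dz),
    dice = list(loss = dice, dlogit = ddice_dz),
    bce_plus_dice = list(loss = bce + dice, dlogit = dbce_dz + ddice_dz)
  )
}
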