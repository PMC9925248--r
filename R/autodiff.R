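# Minimal reverse-mode autodiff tape used by the segmentation network.
#
# Values are plain R arrays of dim (H, W, C, N). Each node is an environment
# holding $value, $grad, $parents (list of nodes) and $backward, a closure
# returning one gradient per parent. Nodes are replayed in reverse creation
# order, which is a valid topological order because ops only consume existing
# nodes. Internal API; nothing here is exported.

ad_tape <- function(training = FALSE) {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp$training <- training
  tp
}

ad_node <- function(tape, value, parents = list(), backward = NULL,
                    param = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$parents <- parents
  nd$backward <- backward
  nd$param <- param
  nd$grad <- NULL
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  nd$id <- tape$n
  tape$nodes[[tape$n]] <- nd
  nd
}

ad_input <- function(tape, value) ad_node(tape, value)

ad_param <- function(tape, value, name) ad_node(tape, value, param = name)

# Backpropagate from scalar node `root`; returns named list of gradients for
# every param node reached.
ad_backward <- function(tape, root) {
  root$grad <- 1
  grads <- list()
  for (i in seq(root$id, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad)) next
    if (!is.null(nd$param)) {
      g <- nd$grad
      grads[[nd$param]] <- if (is.null(grads[[nd$param]])) g else grads[[nd$param]] + g
    }
    if (is.null(nd$backward)) next
    gs <- nd$backward(nd)
    for (p in seq_along(nd$parents)) {
      if (is.null(gs[[p]])) next
      par <- nd$parents[[p]]
      par$grad <- if (is.null(par$grad)) gs[[p]] else par$grad + gs[[p]]
    }
    nd$grad <- NULL # release memory as we go
  }
  grads
}

# ---- tensor helpers ---------------------------------------------------------

as_t4 <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("tensor must have dims")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

# ---- ops --------------------------------------------------------------------

ad_conv2d <- function(tape, x, w, k, rate = 1L) {
  y <- cpp_conv2d_fw(x$value, w$value, as.integer(k), as.integer(rate))
  ad_node(tape, y, list(x, w), function(nd) {
    bw <- cpp_conv2d_bw(x$value, w$value, nd$grad, as.integer(k),
                        as.integer(rate))
    list(bw$gx, bw$gw)
  })
}

ad_dwconv <- function(tape, x, w, k, rate = 1L) {
  y <- cpp_dwconv_fw(x$value, w$value, as.integer(k), as.integer(rate))
  ad_node(tape, y, list(x, w), function(nd) {
    bw <- cpp_dwconv_bw(x$value, w$value, nd$grad, as.integer(k),
                        as.integer(rate))
    list(bw$gx, bw$gw)
  })
}

ad_tconv <- function(tape, x, w) {
  y <- cpp_tconv_fw(x$value, w$value)
  ad_node(tape, y, list(x, w), function(nd) {
    bw <- cpp_tconv_bw(x$value, w$value, nd$grad)
    list(bw$gx, bw$gw)
  })
}

ad_maxpool2 <- function(tape, x) {
  fw <- cpp_maxpool2_fw(x$value)
  xdim <- dim(x$value)
  nd <- ad_node(tape, fw$y, list(x), function(nd) {
    list(cpp_maxpool_bw(nd$grad, nd$idx, as.integer(xdim)))
  })
  nd$idx <- fw$idx
  nd
}

ad_maxpool3 <- function(tape, x) {
  fw <- cpp_maxpool3_fw(x$value)
  xdim <- dim(x$value)
  nd <- ad_node(tape, fw$y, list(x), function(nd) {
    list(cpp_maxpool_bw(nd$grad, nd$idx, as.integer(xdim)))
  })
  nd$idx <- fw$idx
  nd
}

ad_concat <- function(tape, xs) {
  dims <- lapply(xs, function(x) dim(x$value))
  chans <- vapply(dims, `[`, integer(1), 3L)
  d1 <- dims[[1]]
  out <- array(0, c(d1[1], d1[2], sum(chans), d1[4]))
  at <- 0L
  for (i in seq_along(xs)) {
    out[, , at + seq_len(chans[i]), ] <- xs[[i]]$value
    at <- at + chans[i]
  }
  ad_node(tape, out, xs, function(nd) {
    gs <- vector("list", length(xs))
    at <- 0L
    for (i in seq_along(xs)) {
      g <- nd$grad[, , at + seq_len(chans[i]), , drop = FALSE]
      dim(g) <- dims[[i]]
      gs[[i]] <- g
      at <- at + chans[i]
    }
    gs
  })
}

ad_relu <- function(tape, x) {
  y <- pmax(x$value, 0)
  ad_node(tape, y, list(x), function(nd) list(nd$grad * (x$value > 0)))
}

ad_swish <- function(tape, x) {
  ad_node(tape, swish(x$value), list(x),
          function(nd) list(nd$grad * swish_derivative(x$value)))
}

ad_sigmoid <- function(tape, x) {
  s <- sigmoid(x$value)
  ad_node(tape, s, list(x), function(nd) list(nd$grad * s * (1 - s)))
}

ad_dropout <- function(tape, x, rate) {
  if (!tape$training || rate <= 0) return(x)
  keep <- 1 - rate
  mask <- array(stats::rbinom(length(x$value), 1L, keep) / keep,
                dim = dim(x$value))
  ad_node(tape, x$value * mask, list(x), function(nd) list(nd$grad * mask))
}

# Batch normalization over (H, W, N) per channel. `state` is an environment
# carrying running mean/var for inference; updated in training mode.
ad_batchnorm <- function(tape, x, gamma, beta, state, eps = 1e-3,
                         momentum = 0.9) {
  d <- dim(x$value)
  C <- d[3]
  perm <- c(1L, 2L, 4L, 3L)
  xm <- matrix(aperm(x$value, perm), ncol = C) # rows: pixels*batch, cols: ch
  m <- nrow(xm)
  if (tape$training) {
    mu <- colMeans(xm)
    va <- colMeans(xm^2) - mu^2
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var <- momentum * state$var + (1 - momentum) * va
  } else {
    mu <- state$mean
    va <- state$var
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(xm, 2L, mu, "-")
  xhat <- sweep(xhat, 2L, istd, "*")
  ym <- sweep(xhat, 2L, as.numeric(gamma$value), "*")
  ym <- sweep(ym, 2L, as.numeric(beta$value), "+")
  y <- aperm(array(ym, c(d[1], d[2], d[4], C)), c(1L, 2L, 4L, 3L))
  training <- tape$training
  ad_node(tape, y, list(x, gamma, beta), function(nd) {
    gym <- matrix(aperm(nd$grad, perm), ncol = C)
    dbeta <- colSums(gym)
    dgamma <- colSums(gym * xhat)
    dxhat <- sweep(gym, 2L, as.numeric(gamma$value), "*")
    if (training) {
      t1 <- sweep(dxhat, 2L, colMeans(dxhat), "-")
      t2 <- sweep(xhat, 2L, colMeans(dxhat * xhat), "*")
      dxm <- sweep(t1 - t2, 2L, istd, "*")
    } else {
      dxm <- sweep(dxhat, 2L, istd, "*")
    }
    dx <- aperm(array(dxm, c(d[1], d[2], d[4], C)), c(1L, 2L, 4L, 3L))
    list(dx, dgamma, dbeta)
  })
}

# mean binary cross-entropy computed from logits (numerically stable
# softplus form); `target` is a plain array
ad_bce_logits <- function(tape, z, target) {
  zv <- z$value
  sp <- ifelse(zv > 0, zv + log1p(exp(-zv)), log1p(exp(zv)))
  loss <- mean(sp - target * zv)
  n <- length(zv)
  ad_node(tape, loss, list(z),
          function(nd) list(nd$grad * (sigmoid(zv) - target) / n))
}

# soft Dice loss on probabilities
ad_dice_loss <- function(tape, p, target, eps = 1) {
  pv <- p$value
  inter <- sum(pv * target)
  denom <- sum(pv) + sum(target) + eps
  loss <- 1 - (2 * inter + eps) / denom
  ad_node(tape, loss, list(p), function(nd) {
    g <- -(2 * target * denom - (2 * inter + eps)) / denom^2
    list(nd$grad * g)
  })
}

ad_add <- function(tape, a, b) {
  ad_node(tape, a$value + b$value, list(a, b),
          function(nd) list(nd$grad, nd$grad))
}

ad_scale <- function(tape, a, s) {
  ad_node(tape, a$value * s, list(a), function(nd) list(nd$grad * s))
}
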