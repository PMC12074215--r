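# Minimal reverse-mode autodiff over 2-D feature maps, written for the
# oriented detector. A feature map is an (H*W) x C matrix with spatial index
# s = h + H*w (column-major over the image plane; channels in columns), so
# an H x W x 3 image array reshapes to a tensor without copying semantics.
# Vectors (pooled features, gate logits) are plain numeric vectors. Each op
# appends a node holding the value and a backward closure; tape_backward()
# walks the nodes in reverse, accumulating cotangents into parameter
# environments.

tape_ctx <- function(track = TRUE) {
  ctx <- new.env(parent = emptyenv())
  ctx$nodes <- list()
  ctx$n <- 0L
  ctx$track <- track
  ctx$flops <- 0
  ctx
}

tp_node <- function(ctx, val, H = NULL, W = NULL, parents = integer(0),
                    back = NULL, param = NULL) {
  # force the promises before touching the node counter: evaluating `val`
  # (or `parents`) may itself append nodes to the tape, and the new node
  # must come after every node it depends on
  force(val)
  force(H)
  force(W)
  force(parents)
  force(back)
  force(param)
  if (!ctx$track) {
    return(list(id = NA_integer_, val = val, H = H, W = W))
  }
  ctx$n <- ctx$n + 1L
  node <- list(
    id = ctx$n, val = val, H = H, W = W,
    parents = parents, back = back, param = param
  )
  ctx$nodes[[ctx$n]] <- node
  node
}

# parameters: environments with $val, $grad, $mom, $decay (logical)
new_param <- function(M, dims, init = "kaiming", fan_in = NULL, decay = TRUE,
                      gain = 1) {
  p <- new.env(parent = emptyenv())
  n <- prod(dims)
  p$val <- switch(init,
    kaiming = matrix(rnorm(n, 0, gain * sqrt(2 / fan_in)), dims[1], dims[2]),
    zeros = if (length(dims) == 1) numeric(dims) else matrix(0, dims[1], dims[2]),
    ones = if (length(dims) == 1) rep(1, dims) else matrix(1, dims[1], dims[2])
  )
  p$grad <- NULL
  p$mom <- NULL
  p$decay <- decay
  M$params[[length(M$params) + 1L]] <- p
  p
}

new_buffer <- function(M, value) {
  b <- new.env(parent = emptyenv())
  b$val <- value
  M$buffers[[length(M$buffers) + 1L]] <- b
  b
}

tp_param <- function(ctx, p) {
  tp_node(ctx, p$val, param = p)
}

accumulate <- function(grads, id, g) {
  if (is.na(id)) {
    return(grads) # untracked leaf (e.g. the input image)
  }
  if (is.null(grads[[id]])) grads[[id]] <- g else grads[[id]] <- grads[[id]] + g
  grads
}

# roots: list of list(id, grad)
tape_backward <- function(ctx, roots) {
  grads <- vector("list", ctx$n)
  for (r in roots) {
    grads <- accumulate(grads, r$id, r$grad)
  }
  for (i in rev(seq_len(ctx$n))) {
    g <- grads[[i]]
    if (is.null(g)) next
    node <- ctx$nodes[[i]]
    if (!is.null(node$param)) {
      p <- node$param
      if (is.null(p$grad)) p$grad <- g else p$grad <- p$grad + g
      next
    }
    if (!is.null(node$back)) {
      pg <- node$back(g)
      for (j in seq_along(node$parents)) {
        if (!is.null(pg[[j]])) {
          grads <- accumulate(grads, node$parents[j], pg[[j]])
        }
      }
    }
    grads[i] <- list(NULL) # free the cotangent, keep list length
    ctx$nodes[[i]] <- list(id = i) # drop value and closure
  }
  invisible(NULL)
}

conv_out_dim <- function(n, k, stride, pad) (n + 2 * pad - k) %/% stride + 1

# convolution; weight/bias arrive as tape nodes (enables dynamic kernels).
# wnode$val: (k*k*C_in/groups) x C_out with row order (ki + k*kj) + k*k*c.
# groups must be 1 (dense) or C_in (depthwise with C_out == C_in).
op_conv <- function(ctx, x, wnode, bnode = NULL, k = 1, stride = 1,
                    pad = k %/% 2, groups = 1) {
  C_in <- ncol(x$val)
  Ho <- conv_out_dim(x$H, k, stride, pad)
  Wo <- conv_out_dim(x$W, k, stride, pad)
  Wm <- wnode$val
  C_out <- ncol(Wm)
  if (k == 1 && stride == 1 && groups == 1) {
    cols <- x$val
  } else {
    cols <- cpp_im2col(
      x$val, as.integer(x$H), as.integer(x$W), as.integer(k),
      as.integer(stride), as.integer(pad)
    )
  }
  if (groups == 1) {
    y <- cols %*% Wm
  } else {
    stopifnot(groups == C_in, C_out == C_in)
    kk <- k * k
    y <- matrix(0, nrow(cols), C_out)
    for (c in seq_len(C_in)) {
      idx <- ((c - 1) * kk + 1):(c * kk)
      y[, c] <- cols[, idx, drop = FALSE] %*% Wm[idx - (c - 1) * kk, c]
    }
  }
  if (!is.null(bnode)) y <- sweep_add_cols(y, bnode$val)
  macs_per_out <- if (groups == 1) nrow(Wm) else k * k
  ctx$flops <- ctx$flops + 2 * length(y) * macs_per_out +
    if (is.null(bnode)) 0 else length(y)
  parents <- c(x$id, wnode$id, if (!is.null(bnode)) bnode$id)
  back <- function(dy) {
    if (groups == 1) {
      dW <- crossprod(cols, dy)
      dcols <- if (is.na(x$id)) NULL else tcrossprod(dy, Wm)
    } else {
      kk <- k * k
      dW <- matrix(0, nrow(Wm), ncol(Wm))
      dcols <- matrix(0, nrow(cols), ncol(cols))
      for (c in seq_len(C_in)) {
        idx <- ((c - 1) * kk + 1):(c * kk)
        dW[seq_len(kk), c] <- crossprod(cols[, idx, drop = FALSE], dy[, c])
        dcols[, idx] <- tcrossprod(dy[, c, drop = FALSE], Wm[seq_len(kk), c])
      }
    }
    dx <- if (is.null(dcols) || is.na(x$id)) {
      NULL # untracked leaf (the input image): skip the expensive col2im
    } else if (k == 1 && stride == 1 && groups == 1) {
      dcols
    } else {
      cpp_col2im(
        dcols, as.integer(C_in), as.integer(x$H), as.integer(x$W),
        as.integer(k), as.integer(stride), as.integer(pad)
      )
    }
    out <- list(dx, dW)
    if (!is.null(bnode)) out <- c(out, list(colSums(dy)))
    out
  }
  tp_node(ctx, y, Ho, Wo, parents, back)
}

# add a per-channel vector to all rows (columns are channels)
sweep_add_cols <- function(m, v) {
  m + rep(v, each = nrow(m))
}

# batch normalization over the spatial axis (single-image batch statistics
# during training; exponential running stats for inference)
op_bn <- function(ctx, x, gnode, bnode, rmean, rvar, training,
                  momentum = 0.1, eps = 1e-4) {
  v <- x$val
  if (training) {
    st <- cpp_col_stats(v)
    mu <- st$mu
    va <- st$va
    rmean$val <- (1 - momentum) * rmean$val + momentum * mu
    rvar$val <- (1 - momentum) * rvar$val + momentum * va
  } else {
    mu <- rmean$val
    va <- rvar$val
  }
  istd <- 1 / sqrt(va + eps)
  y <- cpp_bn_forward(v, mu, istd, gnode$val, bnode$val)
  back <- function(dy) {
    r <- cpp_bn_backward(v, dy, mu, istd, gnode$val, training)
    list(r$dx, r$dg, r$db)
  }
  tp_node(ctx, y, x$H, x$W, c(x$id, gnode$id, bnode$id), back)
}

op_silu <- function(ctx, x) {
  if (is.matrix(x$val)) {
    y <- cpp_silu(x$val)
    tp_node(ctx, y, x$H, x$W, x$id, function(dy) {
      list(cpp_silu_backward(x$val, dy))
    })
  } else {
    s <- 1 / (1 + exp(-x$val))
    tp_node(ctx, x$val * s, x$H, x$W, x$id, function(dy) {
      list(dy * s * (1 + x$val * (1 - s)))
    })
  }
}

op_sigmoid <- function(ctx, x) {
  s <- 1 / (1 + exp(-x$val))
  tp_node(ctx, s, x$H, x$W, x$id, function(dy) list(dy * s * (1 - s)))
}

op_relu <- function(ctx, x) {
  y <- pmax(x$val, 0)
  tp_node(ctx, y, x$H, x$W, x$id, function(dy) list(dy * (x$val > 0)))
}

op_add <- function(ctx, a, b) {
  tp_node(ctx, a$val + b$val, a$H, a$W, c(a$id, b$id), function(dy) {
    list(dy, dy)
  })
}

# channel-wise gating: y[, c] = x[, c] * s[c]
op_scale_channels <- function(ctx, x, s) {
  S <- nrow(x$val)
  tp_node(ctx, x$val * rep(s$val, each = S), x$H, x$W, c(x$id, s$id),
    function(dy) {
      list(dy * rep(s$val, each = S), colSums(dy * x$val))
    }
  )
}

# global average pool to a channel vector
op_gap <- function(ctx, x) {
  S <- nrow(x$val)
  C <- ncol(x$val)
  tp_node(ctx, colMeans(x$val), NULL, NULL, x$id, function(dy) {
    list(matrix(rep(dy / S, each = S), S, C))
  })
}

# fully connected: W (out x in)
op_fc <- function(ctx, v, wnode, bnode) {
  y <- as.numeric(wnode$val %*% v$val) + bnode$val
  ctx$flops <- ctx$flops + 2 * length(wnode$val) + length(y)
  tp_node(ctx, y, NULL, NULL, c(v$id, wnode$id, bnode$id), function(dy) {
    list(
      as.numeric(crossprod(wnode$val, dy)),
      outer(dy, as.numeric(v$val)), dy
    )
  })
}

op_softmax <- function(ctx, v, temperature = 1) {
  z <- v$val / temperature
  z <- z - max(z)
  e <- exp(z)
  y <- e / sum(e)
  tp_node(ctx, y, NULL, NULL, v$id, function(dy) {
    list((y * (dy - sum(dy * y))) / temperature)
  })
}

# convex mixture of parameter nodes: val = sum_k w[k] * P_k
op_mix <- function(ctx, wts, pnodes) {
  K <- length(pnodes)
  val <- wts$val[1] * pnodes[[1]]$val
  for (k in seq_len(K)[-1]) val <- val + wts$val[k] * pnodes[[k]]$val
  parents <- c(wts$id, vapply(pnodes, function(p) p$id, integer(1)))
  back <- function(dy) {
    dw <- vapply(pnodes, function(p) sum(p$val * dy), numeric(1))
    c(list(dw), lapply(seq_len(K), function(k) wts$val[k] * dy))
  }
  tp_node(ctx, val, NULL, NULL, parents, back)
}

op_concat <- function(ctx, xs) {
  val <- do.call(cbind, lapply(xs, function(x) x$val))
  sizes <- vapply(xs, function(x) ncol(x$val), integer(1))
  tp_node(ctx, val, xs[[1]]$H, xs[[1]]$W,
    vapply(xs, function(x) x$id, integer(1)),
    function(dy) {
      off <- cumsum(c(0, sizes))
      lapply(seq_along(xs), function(i) {
        dy[, (off[i] + 1):off[i + 1], drop = FALSE]
      })
    }
  )
}

# columns lo:hi of a wider map (channel slice)
op_slice <- function(ctx, x, lo, hi) {
  tp_node(ctx, x$val[, lo:hi, drop = FALSE], x$H, x$W, x$id, function(dy) {
    d <- matrix(0, nrow(x$val), ncol(x$val))
    d[, lo:hi] <- dy
    list(d)
  })
}

op_maxpool <- function(ctx, x, k = 5) {
  res <- cpp_maxpool_same(x$val, as.integer(x$H), as.integer(x$W),
    as.integer(k))
  arg <- res$arg
  tp_node(ctx, res$y, x$H, x$W, x$id, function(dy) {
    list(cpp_maxpool_same_backward(dy, arg))
  })
}

op_upsample2 <- function(ctx, x) {
  H <- x$H
  W <- x$W
  H2 <- 2L * H
  W2 <- 2L * W
  h2 <- rep(0:(H2 - 1), times = W2)
  w2 <- rep(0:(W2 - 1), each = H2)
  src <- (h2 %/% 2) + H * (w2 %/% 2) + 1
  y <- x$val[src, , drop = FALSE]
  tp_node(ctx, y, H2, W2, x$id, function(dy) {
    dx <- matrix(0, H * W, ncol(x$val))
    for (dh in 0:1) {
      for (dw in 0:1) {
        idx <- rep(2 * (0:(H - 1)) + dh, times = W) +
          H2 * rep(2 * (0:(W - 1)) + dw, each = H) + 1
        dx <- dx + dy[idx, , drop = FALSE]
      }
    }
    list(dx)
  })
}

# stochastic depth on a residual branch: during training the branch is
# dropped entirely with probability p (and scaled by 1/(1-p) otherwise)
op_droppath <- function(ctx, x, p, training) {
  if (!training || p <= 0) {
    return(x)
  }
  if (runif(1) < p) {
    tp_node(ctx, x$val * 0, x$H, x$W, x$id, function(dy) list(dy * 0))
  } else {
    sc <- 1 / (1 - p)
    tp_node(ctx, x$val * sc, x$H, x$W, x$id, function(dy) list(dy * sc))
  }
}

op_matmul <- function(ctx, a, b) {
  y <- a$val %*% b$val
  ctx$flops <- ctx$flops + 2 * nrow(a$val) * ncol(a$val) * ncol(b$val)
  tp_node(ctx, y, a$H, a$W, c(a$id, b$id), function(dy) {
    list(tcrossprod(dy, b$val), crossprod(a$val, dy))
  })
}

# y = a %*% t(b)
op_matmul_tb <- function(ctx, a, b) {
  y <- tcrossprod(a$val, b$val)
  ctx$flops <- ctx$flops + 2 * nrow(a$val) * ncol(a$val) * nrow(b$val)
  tp_node(ctx, y, a$H, a$W, c(a$id, b$id), function(dy) {
    list(dy %*% b$val, crossprod(dy, a$val))
  })
}

op_row_softmax <- function(ctx, m, scale = 1) {
  z <- m$val * scale
  z <- z - apply(z, 1, max)
  e <- exp(z)
  y <- e / rowSums(e)
  tp_node(ctx, y, m$H, m$W, m$id, function(dy) {
    list((y * (dy - rowSums(dy * y))) * scale)
  })
}
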