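# Building blocks of the oriented detector. Each constructor registers its
# parameters in the model registry M (an environment with $params, $buffers)
# and returns list(forward = function(ctx, x, train) node). Feature maps are
# (H*W) x C matrices; conv weights are (k*k*C_in) x C_out with row order
# (ki + k*kj) + k*k*c (depthwise: (k*k) x C).

new_registry <- function() {
  M <- new.env(parent = emptyenv())
  M$params <- list()
  M$buffers <- list()
  M
}

make_divisible <- function(v, divisor = 8) {
  max(divisor, round(v / divisor) * divisor)
}

# conv + batch norm + SiLU (the foundational feature-extraction unit)
conv_unit <- function(M, c_in, c_out, k = 1, s = 1, g = 1, act = TRUE) {
  wdims <- if (g == 1) c(k * k * c_in, c_out) else c(k * k, c_out)
  w <- new_param(M, wdims, "kaiming", fan_in = wdims[1])
  gamma <- new_param(M, c_out, "ones", decay = FALSE)
  beta <- new_param(M, c_out, "zeros", decay = FALSE)
  rm <- new_buffer(M, rep(0, c_out))
  rv <- new_buffer(M, rep(1, c_out))
  list(forward = function(ctx, x, train) {
    y <- op_conv(ctx, x, tp_param(ctx, w), NULL, k, s, k %/% 2, g)
    y <- op_bn(ctx, y, tp_param(ctx, gamma), tp_param(ctx, beta), rm, rv, train)
    if (act) op_silu(ctx, y) else y
  })
}

# squeeze-and-excitation: channel attention from globally pooled statistics
se_unit <- function(M, c, c_se) {
  w1 <- new_param(M, c(c_se, c), "kaiming", fan_in = c)
  b1 <- new_param(M, c_se, "zeros", decay = FALSE)
  w2 <- new_param(M, c(c, c_se), "kaiming", fan_in = c_se)
  b2 <- new_param(M, c, "zeros", decay = FALSE)
  list(forward = function(ctx, x, train) {
    v <- op_gap(ctx, x)
    h <- op_silu(ctx, op_fc(ctx, v, tp_param(ctx, w1), tp_param(ctx, b1)))
    s <- op_sigmoid(ctx, op_fc(ctx, h, tp_param(ctx, w2), tp_param(ctx, b2)))
    op_scale_channels(ctx, x, s)
  })
}

# Fused-MBConv: a single 3x3 standard convolution replaces the expansion +
# depthwise pair (plus a 1x1 projection when the expansion ratio exceeds 1)
fused_mbconv <- function(M, c_in, c_out, e, s, sd_prob = 0) {
  c_mid <- c_in * e
  if (e == 1) {
    main <- conv_unit(M, c_in, c_out, 3, s)
    fwd <- function(ctx, x, train) main$forward(ctx, x, train)
  } else {
    expand <- conv_unit(M, c_in, c_mid, 3, s)
    project <- conv_unit(M, c_mid, c_out, 1, 1, act = FALSE)
    fwd <- function(ctx, x, train) {
      project$forward(ctx, expand$forward(ctx, x, train), train)
    }
  }
  use_res <- s == 1 && c_in == c_out
  list(forward = function(ctx, x, train) {
    y <- fwd(ctx, x, train)
    if (use_res) op_add(ctx, x, op_droppath(ctx, y, sd_prob, train)) else y
  })
}

# MBConv: 1x1 expand -> 3x3 depthwise -> SE -> 1x1 project
mbconv <- function(M, c_in, c_out, e, s, se_ratio = 0.25, sd_prob = 0) {
  c_mid <- c_in * e
  expand <- conv_unit(M, c_in, c_mid, 1, 1)
  dw <- conv_unit(M, c_mid, c_mid, 3, s, g = c_mid)
  se <- if (se_ratio > 0) {
    se_unit(M, c_mid, max(1, round(c_in * se_ratio)))
  }
  project <- conv_unit(M, c_mid, c_out, 1, 1, act = FALSE)
  use_res <- s == 1 && c_in == c_out
  list(forward = function(ctx, x, train) {
    y <- expand$forward(ctx, x, train)
    y <- dw$forward(ctx, y, train)
    if (!is.null(se)) y <- se$forward(ctx, y, train)
    y <- project$forward(ctx, y, train)
    if (use_res) op_add(ctx, x, op_droppath(ctx, y, sd_prob, train)) else y
  })
}

# SPPF: three chained 5x5 max-pools concatenated with the input
sppf_unit <- function(M, c_in, c_out) {
  c_mid <- c_in %/% 2
  cv1 <- conv_unit(M, c_in, c_mid, 1)
  cv2 <- conv_unit(M, c_mid * 4, c_out, 1)
  list(forward = function(ctx, x, train) {
    y <- cv1$forward(ctx, x, train)
    p1 <- op_maxpool(ctx, y, 5)
    p2 <- op_maxpool(ctx, p1, 5)
    p3 <- op_maxpool(ctx, p2, 5)
    cv2$forward(ctx, op_concat(ctx, list(y, p1, p2, p3)), train)
  })
}

# dynamic convolution: K parallel kernels fused by an input-conditioned
# softmax gate computed from globally pooled features
dynamic_conv_unit <- function(M, c_in, c_out, k = 3, K = 4,
                              temperature_buf = NULL, gate_hidden = NULL) {
  c1 <- if (is.null(gate_hidden)) max(c_in %/% 4, 4) else gate_hidden
  kernels <- lapply(seq_len(K), function(i) {
    new_param(M, c(k * k * c_in, c_out), "kaiming", fan_in = k * k * c_in)
  })
  biases <- lapply(seq_len(K), function(i) {
    new_param(M, c_out, "zeros", decay = FALSE)
  })
  gw1 <- new_param(M, c(c1, c_in), "kaiming", fan_in = c_in)
  gb1 <- new_param(M, c1, "zeros", decay = FALSE)
  gw2 <- new_param(M, c(K, c1), "kaiming", fan_in = c1)
  gb2 <- new_param(M, K, "zeros", decay = FALSE)
  gamma <- new_param(M, c_out, "ones", decay = FALSE)
  beta <- new_param(M, c_out, "zeros", decay = FALSE)
  rm <- new_buffer(M, rep(0, c_out))
  rv <- new_buffer(M, rep(1, c_out))
  temp <- if (is.null(temperature_buf)) new_buffer(M, 1) else temperature_buf
  list(forward = function(ctx, x, train) {
    v <- op_gap(ctx, x)
    h <- op_relu(ctx, op_fc(ctx, v, tp_param(ctx, gw1), tp_param(ctx, gb1)))
    z <- op_fc(ctx, h, tp_param(ctx, gw2), tp_param(ctx, gb2))
    pi_k <- op_softmax(ctx, z, temp$val)
    wmix <- op_mix(ctx, pi_k, lapply(kernels, function(p) tp_param(ctx, p)))
    bmix <- op_mix(ctx, pi_k, lapply(biases, function(p) tp_param(ctx, p)))
    y <- op_conv(ctx, x, wmix, bmix, k, 1, k %/% 2)
    y <- op_bn(ctx, y, tp_param(ctx, gamma), tp_param(ctx, beta), rm, rv, train)
    op_silu(ctx, y)
  })
}

# C3k2 bottleneck: two 3x3 convs with a residual; the dynamic variant
# replaces the second conv by a dynamic convolution
c3k2_bottleneck <- function(M, c, dconv = FALSE, K = 4, temp = NULL) {
  cv1 <- conv_unit(M, c, c, 3)
  cv2 <- if (dconv) {
    dynamic_conv_unit(M, c, c, 3, K, temp)
  } else {
    conv_unit(M, c, c, 3)
  }
  list(forward = function(ctx, x, train) {
    op_add(ctx, x, cv2$forward(ctx, cv1$forward(ctx, x, train), train))
  })
}

# C3k2 (C2f-style split/aggregate block of paired small convolutions)
c3k2_unit <- function(M, c_in, c_out, n = 1, dconv = FALSE, e = 0.5,
                      K = 4, temp = NULL) {
  c_h <- make_divisible(c_out * e, 4)
  cv1 <- conv_unit(M, c_in, 2 * c_h, 1)
  blocks <- lapply(seq_len(n), function(i) {
    c3k2_bottleneck(M, c_h, dconv, K, temp)
  })
  cv2 <- conv_unit(M, (2 + n) * c_h, c_out, 1)
  list(forward = function(ctx, x, train) {
    y <- cv1$forward(ctx, x, train)
    parts <- list(
      op_slice(ctx, y, 1, c_h),
      op_slice(ctx, y, c_h + 1, 2 * c_h)
    )
    cur <- parts[[2]]
    for (blk in blocks) {
      cur <- blk$forward(ctx, cur, train)
      parts[[length(parts) + 1]] <- cur
    }
    cv2$forward(ctx, op_concat(ctx, parts), train)
  })
}

# position-sensitive attention block (single head) + feed-forward, used in
# C2PSA on the deepest feature map
psa_block <- function(M, c) {
  qk <- max(8, c %/% 2)
  wq <- conv_unit(M, c, qk, 1, act = FALSE)
  wk <- conv_unit(M, c, qk, 1, act = FALSE)
  wv <- conv_unit(M, c, c, 1, act = FALSE)
  proj <- conv_unit(M, c, c, 1, act = FALSE)
  ff1 <- conv_unit(M, c, 2 * c, 1)
  ff2 <- conv_unit(M, 2 * c, c, 1, act = FALSE)
  list(forward = function(ctx, x, train) {
    q <- wq$forward(ctx, x, train)
    k <- wk$forward(ctx, x, train)
    v <- wv$forward(ctx, x, train)
    a <- op_row_softmax(ctx, op_matmul_tb(ctx, q, k), scale = 1 / sqrt(qk))
    att <- op_matmul(ctx, a, v) # (S x S) %*% (S x c)
    att$H <- x$H
    att$W <- x$W
    y <- op_add(ctx, x, proj$forward(ctx, att, train))
    op_add(ctx, y, ff2$forward(ctx, ff1$forward(ctx, y, train), train))
  })
}

c2psa_unit <- function(M, c, n = 1) {
  c_h <- c %/% 2
  cv1 <- conv_unit(M, c, 2 * c_h, 1)
  blocks <- lapply(seq_len(n), function(i) psa_block(M, c_h))
  cv2 <- conv_unit(M, 2 * c_h, c, 1)
  list(forward = function(ctx, x, train) {
    y <- cv1$forward(ctx, x, train)
    a <- op_slice(ctx, y, 1, c_h)
    b <- op_slice(ctx, y, c_h + 1, 2 * c_h)
    for (blk in blocks) b <- blk$forward(ctx, b, train)
    cv2$forward(ctx, op_concat(ctx, list(a, b)), train)
  })
}

# decoupled detection branch: box (distances or direct offsets), class
# scores and the angular branch, each a small conv stack
detect_branch <- function(M, c_in, nc, reg_max, direct) {
  c_h <- max(16, c_in)
  box_out <- if (direct) 4L else 4L * reg_max
  cv_box <- list(
    conv_unit(M, c_in, c_h, 3),
    conv_unit(M, c_h, c_h, 3)
  )
  w_box <- new_param(M, c(c_h, box_out), "kaiming", fan_in = c_h)
  b_box <- new_param(M, box_out, "zeros", decay = FALSE)
  cv_cls <- list(
    conv_unit(M, c_in, c_h, 3),
    conv_unit(M, c_h, c_h, 3)
  )
  w_cls <- new_param(M, c(c_h, nc), "kaiming", fan_in = c_h)
  b_cls <- new_param(M, nc, "zeros", decay = FALSE)
  cv_ang <- conv_unit(M, c_in, c_h, 3)
  w_ang <- new_param(M, c(c_h, 1), "kaiming", fan_in = c_h)
  b_ang <- new_param(M, 1, "zeros", decay = FALSE)
  # start detections rare and box sizes near the object prior
  b_cls$val[] <- -4
  if (direct) b_box$val[] <- c(0, 0, log(5), log(1.2))
  list(forward = function(ctx, x, train) {
    hb <- cv_box[[2]]$forward(ctx, cv_box[[1]]$forward(ctx, x, train), train)
    box <- op_conv(ctx, hb, tp_param(ctx, w_box), tp_param(ctx, b_box), 1)
    hc <- cv_cls[[2]]$forward(ctx, cv_cls[[1]]$forward(ctx, x, train), train)
    cls <- op_conv(ctx, hc, tp_param(ctx, w_cls), tp_param(ctx, b_cls), 1)
    ha <- cv_ang$forward(ctx, x, train)
    ang <- op_conv(ctx, ha, tp_param(ctx, w_ang), tp_param(ctx, b_ang), 1)
    list(box = box, cls = cls, ang = ang)
  })
}

#' Dynamic-convolution attention weights (pure functional form)
#'
#' Computes the softmax gate over K parallel kernels from a feature map:
#' global average pooling condenses the map to a channel vector, a two-layer
#' perceptron produces K logits, and a temperature-scaled softmax normalizes
#' them into mixture weights that sum to one.
#'
#' @param x A feature map: `C x H x W` array or `C x (H*W)` matrix (channels
#'   in rows).
#' @param gate A list with `W1` (`C1 x C`), `b1`, `W2` (`K x C1`), `b2` and
#'   `temperature` (positive scalar, default 1).
#' @return A length-K probability vector.
#' @export
gate_weights <- function(x, gate) {
  m <- if (length(dim(x)) == 3) {
    matrix(x, dim(x)[1], dim(x)[2] * dim(x)[3])
  } else {
    x
  }
  if (ncol(gate$W1) != nrow(m) || nrow(gate$W2) < 1 ||
    ncol(gate$W2) != nrow(gate$W1)) {
    rlang::abort("gate shapes inconsistent with input channels",
      class = "panicleobb_config_error"
    )
  }
  temp <- if (is.null(gate$temperature)) 1 else gate$temperature
  stopifnot(temp > 0)
  pooled <- rowMeans(m)
  h <- pmax(as.numeric(gate$W1 %*% pooled) + gate$b1, 0)
  z <- (as.numeric(gate$W2 %*% h) + gate$b2) / temp
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Dynamic convolution (pure functional form)
#'
#' Fuses K parallel kernels with input-dependent attention weights
#' (`W(x) = sum_k pi_k(x) W_k`, same for biases) and applies the fused
#' kernel as a stride-1 "same"-padded convolution. By linearity this equals
#' the attention-weighted sum of the K individual convolutions.
#'
#' @param x A `C x H x W` array.
#' @param bank A list with `kernels` (list of K `C_out x C_in x k x k`
#'   arrays) and `biases` (list of K length-`C_out` vectors).
#' @param gate Gate parameters as in [gate_weights()].
#' @return A `C_out x H x W` array.
#' @export
dynamic_conv <- function(x, bank, gate) {
  K <- length(bank$kernels)
  stopifnot(K >= 2, length(bank$biases) == K)
  d <- dim(bank$kernels[[1]])
  if (d[2] != dim(x)[1]) {
    rlang::abort("kernel input channels do not match the feature map",
      class = "panicleobb_config_error"
    )
  }
  pi_k <- gate_weights(x, gate)
  wmix <- Reduce(`+`, Map(function(p, w) p * w, pi_k, bank$kernels))
  bmix <- Reduce(`+`, Map(function(p, b) p * b, pi_k, bank$biases))
  conv2d_forward(x, wmix, bmix, stride = 1)
}

#' Plain 2-D convolution of a feature map (reference implementation)
#'
#' Stride-`stride`, zero-padded "same" convolution used by
#' [dynamic_conv()] and available directly for tests and experiments.
#'
#' @param x A `C_in x H x W` array.
#' @param kernel A `C_out x C_in x k x k` array.
#' @param bias A length-`C_out` vector (or `NULL`).
#' @param stride Convolution stride.
#' @return A `C_out x H' x W'` array.
#' @export
conv2d_forward <- function(x, kernel, bias = NULL, stride = 1) {
  d <- dim(x)
  kd <- dim(kernel)
  k <- kd[3]
  pad <- k %/% 2
  xm <- t(matrix(x, d[1], d[2] * d[3])) # S x C
  cols <- cpp_im2col(xm, as.integer(d[2]), as.integer(d[3]), as.integer(k),
    as.integer(stride), as.integer(pad))
  # reorder kernel to the im2col column layout: (ki + k*kj) + k*k*c
  wm <- matrix(aperm(kernel, c(3, 4, 2, 1)), k * k * kd[2], kd[1])
  y <- cols %*% wm
  if (!is.null(bias)) y <- y + rep(bias, each = nrow(y))
  Ho <- conv_out_dim(d[2], k, stride, pad)
  Wo <- conv_out_dim(d[3], k, stride, pad)
  array(t(y), c(kd[1], Ho, Wo))
}
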