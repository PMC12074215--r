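random_gate <- function(C, K = 4, C1 = 8, temperature = 1) {
  list(
    W1 = matrix(rnorm(C1 * C), C1, C), b1 = rnorm(C1),
    W2 = matrix(rnorm(K * C1), K, C1), b2 = rnorm(K),
    temperature = temperature
  )
}

random_bank <- function(K, c_out, c_in, k = 3) {
  list(
    kernels = lapply(seq_len(K), function(i) {
      array(rnorm(c_out * c_in * k * k, 0, 0.2), c(c_out, c_in, k, k))
    }),
    biases = lapply(seq_len(K), function(i) rnorm(c_out, 0, 0.1))
  )
}

test_that("gate weights form a probability vector under any input", {
  set.seed(131)
  for (i in 1:25) {
    C <- sample(2:16, 1)
    x <- array(rnorm(C * 36), c(C, 6, 6))
    g <- random_gate(C, K = sample(2:6, 1))
    w <- gate_weights(x, g)
    expect_equal(sum(w), 1, tolerance = 1e-6)
    expect_true(all(w >= 0 & w <= 1))
  }

  # zero logits: uniform; saturated bias: one-hot
  C <- 8
  x <- array(rnorm(C * 16), c(C, 4, 4))
  g0 <- random_gate(C, K = 4)
  g0$W2[] <- 0
  g0$b2[] <- 0
  expect_equal(gate_weights(x, g0), rep(0.25, 4))
  g1 <- g0
  g1$b2 <- c(100, 0, 0, 0)
  w <- gate_weights(x, g1)
  expect_equal(w[1], 1, tolerance = 1e-20)
  expect_lt(max(w[-1]), 1e-20)

  # constant map pools to the constant: weights equal those of a 1x1 map
  xc <- array(2.5, c(C, 5, 5))
  x1 <- array(2.5, c(C, 1, 1))
  g <- random_gate(C)
  expect_equal(gate_weights(xc, g), gate_weights(x1, g))

  expect_error(gate_weights(array(0, c(3, 2, 2)), random_gate(5)),
    class = "panicleobb_config_error"
  )
})

test_that("temperature drives the gate between uniform and argmax", {
  set.seed(141)
  g <- random_gate(6, K = 4)
  x <- array(rnorm(6 * 9), c(6, 3, 3))
  entropy <- function(p) -sum(p * log(pmax(p, 1e-300)))
  temps <- c(0.01, 0.1, 1, 10, 1000)
  ents <- vapply(temps, function(tt) {
    g$temperature <- tt
    entropy(gate_weights(x, g))
  }, numeric(1))
  expect_true(all(diff(ents) >= -1e-9)) # monotone in temperature
  g$temperature <- 1e-4
  expect_equal(max(gate_weights(x, g)), 1, tolerance = 1e-9)
  g$temperature <- 1e6
  expect_equal(gate_weights(x, g), rep(0.25, 4), tolerance = 1e-4)
})

test_that("dynamic convolution reduces to static conv for degenerate gates
           and is linear in the kernel mixture", {
  set.seed(151)
  x <- array(rnorm(3 * 8 * 8), c(3, 8, 8))

  # identical kernels: any gate yields the static convolution
  bank <- random_bank(4, 5, 3)
  for (k in 2:4) bank$kernels[[k]] <- bank$kernels[[1]]
  for (k in 2:4) bank$biases[[k]] <- bank$biases[[1]]
  g <- random_gate(3)
  expect_equal(
    dynamic_conv(x, bank, g),
    conv2d_forward(x, bank$kernels[[1]], bank$biases[[1]]),
    tolerance = 1e-10
  )

  # one-hot gate selects kernel j
  bank2 <- random_bank(4, 5, 3)
  g2 <- random_gate(3)
  g2$W2[] <- 0
  g2$b2 <- c(0, 1000, 0, 0)
  expect_equal(
    dynamic_conv(x, bank2, g2),
    conv2d_forward(x, bank2$kernels[[2]], bank2$biases[[2]]),
    tolerance = 1e-8
  )

  # aggregate-then-convolve equals convolve-then-aggregate
  for (i in 1:10) {
    C_in <- sample(2:5, 1)
    C_out <- sample(2:6, 1)
    xi <- array(rnorm(C_in * 49), c(C_in, 7, 7))
    bk <- random_bank(4, C_out, C_in)
    gt <- random_gate(C_in)
    pi_k <- gate_weights(xi, gt)
    split_route <- Reduce(`+`, lapply(1:4, function(k) {
      pi_k[k] * conv2d_forward(xi, bk$kernels[[k]], bk$biases[[k]])
    }))
    expect_equal(dynamic_conv(xi, bk, gt), split_route, tolerance = 1e-5)
  }
})

test_that("conv2d_forward matches a naive nested-loop convolution", {
  set.seed(161)
  x <- array(rnorm(2 * 5 * 5), c(2, 5, 5))
  kern <- array(rnorm(3 * 2 * 3 * 3), c(3, 2, 3, 3))
  bias <- rnorm(3)
  got <- conv2d_forward(x, kern, bias)
  want <- array(0, c(3, 5, 5))
  for (co in 1:3) {
    for (i in 1:5) {
      for (j in 1:5) {
        acc <- bias[co]
        for (ci in 1:2) {
          for (ki in 1:3) {
            for (kj in 1:3) {
              ii <- i + ki - 2
              jj <- j + kj - 2
              if (ii >= 1 && ii <= 5 && jj >= 1 && jj <= 5) {
                acc <- acc + x[ci, ii, jj] * kern[co, ci, ki, kj]
              }
            }
          }
        }
        want[co, i, j] <- acc
      }
    }
  }
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("backbone construction follows the stage table", {
  bb <- build_backbone(backbone_spec())
  expect_equal(bb$stage_blocks, c(1, 2, 4, 4, 6, 9, 15))
  expect_equal(bb$tap_channels, c(64, 160, 256))
  expect_equal(bb$tap_strides, c(8, 16, 32))

  half <- panicleobb:::scaled_stages(backbone_spec(width_mult = 0.5))
  expect_equal(half$channels_scaled, c(16, 16, 24, 32, 64, 80, 128))
  expect_true(all(half$channels_scaled %% 8 == 0))

  # output strides are invariant to the input size
  tiny <- build_backbone(backbone_spec(width_mult = 1 / 3, depth_mult = 0.1))
  for (size in c(96, 160)) {
    ctx <- panicleobb:::tape_ctx(track = FALSE)
    x <- list(
      id = NA_integer_, val = matrix(0, size^2, 3), H = size, W = size
    )
    taps <- tiny$forward(ctx, x)
    expect_equal(
      vapply(taps, function(t) t$H, numeric(1)),
      c(p3 = size / 8, p4 = size / 16, p5 = size / 32)
    )
  }
})

test_that("detector assembly respects head flags and output contracts", {
  cfg0 <- model_config(
    width_mult = 0.125, depth_mult = 0.07,
    head_dconv = c(FALSE, FALSE, FALSE)
  )
  cfg1 <- model_config(
    width_mult = 0.125, depth_mult = 0.07,
    head_dconv = c(TRUE, TRUE, TRUE)
  )
  m0 <- build_oe_yolo(cfg0, seed = 1)
  m1 <- build_oe_yolo(cfg1, seed = 1)
  # without dynamic blocks the model has strictly fewer parameter tensors
  expect_lt(length(m0$M$params), length(m1$M$params))

  ctx <- panicleobb:::tape_ctx(track = FALSE)
  size <- 96
  x <- list(id = NA_integer_, val = matrix(
    runif(size^2 * 3), size^2, 3
  ), H = size, W = size)
  outs <- m1$forward(ctx, x, train = FALSE)
  expect_named(outs, c("p3", "p4", "p5"))
  for (lev in 1:3) {
    o <- outs[[lev]]
    expect_equal(o$box$H, size / m1$strides[lev])
    expect_equal(ncol(o$box$val), 4 * cfg1$reg_max)
    expect_equal(ncol(o$cls$val), 1)
    expect_equal(ncol(o$ang$val), 1)
    expect_true(all(is.finite(o$box$val)))
    dec <- panicleobb:::decode_raw(
      o$box$val, o$ang$val, m1$strides[lev], o$box$H, o$box$W, "dfl", 16
    )
    expect_true(all(dec$theta >= -pi / 2 & dec$theta < pi / 2))
  }

  # inference is deterministic even with stochastic depth configured
  m2 <- build_oe_yolo(model_config(
    width_mult = 0.125, depth_mult = 0.07,
    drop_path = 0.3
  ), seed = 2)
  o1 <- m2$forward(panicleobb:::tape_ctx(FALSE), x, train = FALSE)
  o2 <- m2$forward(panicleobb:::tape_ctx(FALSE), x, train = FALSE)
  expect_identical(o1$p3$box$val, o2$p3$box$val)

  expect_error(model_config(head_dconv = c(TRUE, FALSE)),
    class = "panicleobb_config_error"
  )
})

test_that("complexity accounting counts parameters and FLOPs", {
  # a bare 3x3 conv, 3 -> 16 channels with bias
  M <- panicleobb:::new_registry()
  panicleobb:::new_param(M, c(27, 16), "kaiming", fan_in = 27)
  panicleobb:::new_param(M, 16, "zeros")
  expect_equal(model_complexity(list(M = M))$params, 3 * 3 * 3 * 16 + 16)

  # FLOPs of a single dense conv layer at a known size: 2*K*C_out*S MACs
  mini <- build_backbone(backbone_spec(width_mult = 1 / 3, depth_mult = 0.1))
  cc <- model_complexity(mini, input_size = 64)
  expect_true(cc$flops > 0)
})

test_that("tape gradients match finite differences through the full model", {
  m <- build_oe_yolo(
    model_config(width_mult = 0.125, depth_mult = 0.07, box_mode = "direct"),
    seed = 3
  )
  set.seed(171)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  # a fixed linear functional of the three head outputs: its tape gradient
  # exercises every layer, and its finite differences are exact up to
  # second order
  cots <- NULL
  run <- function() {
    ctx <- panicleobb:::tape_ctx(TRUE)
    outs <- m$forward(ctx, panicleobb:::img_to_tensor(img), train = TRUE)
    if (is.null(cots)) {
      cots <<- lapply(outs, function(o) {
        list(
          box = matrix(rnorm(length(o$box$val), 0, 0.1), nrow(o$box$val)),
          cls = matrix(rnorm(length(o$cls$val), 0, 0.1), nrow(o$cls$val)),
          ang = matrix(rnorm(length(o$ang$val), 0, 0.1), nrow(o$ang$val))
        )
      })
    }
    j <- 0
    roots <- list()
    for (lev in 1:3) {
      j <- j + sum(cots[[lev]]$box * outs[[lev]]$box$val) +
        sum(cots[[lev]]$cls * outs[[lev]]$cls$val) +
        sum(cots[[lev]]$ang * outs[[lev]]$ang$val)
      roots <- c(roots, list(
        list(id = outs[[lev]]$box$id, grad = cots[[lev]]$box),
        list(id = outs[[lev]]$cls$id, grad = cots[[lev]]$cls),
        list(id = outs[[lev]]$ang$id, grad = cots[[lev]]$ang)
      ))
    }
    list(ctx = ctx, j = j, roots = roots)
  }
  r <- run()
  panicleobb:::tape_backward(r$ctx, r$roots)
  expect_equal(
    sum(vapply(m$M$params, function(p) is.null(p$grad), logical(1))), 0
  )
  set.seed(181)
  picks <- sample(length(m$M$params), 6)
  for (pi in picks) {
    p <- m$M$params[[pi]]
    idx <- sample(length(p$val), 1)
    g_tape <- p$grad[idx]
    eps <- 1e-4
    v0 <- p$val[idx]
    p$val[idx] <- v0 + eps
    j1 <- run()$j
    p$val[idx] <- v0 - eps
    j2 <- run()$j
    p$val[idx] <- v0
    fd <- (j1 - j2) / (2 * eps)
    expect_lt(abs(g_tape - fd), 1e-4 + 1e-2 * abs(fd))
  }
})

test_that("checkpoints round-trip through save_model/load_model", {
  m <- build_oe_yolo(
    model_config(width_mult = 0.125, depth_mult = 0.07),
    seed = 4
  )
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  m2 <- load_model(path)
  size <- 64
  x <- list(id = NA_integer_, val = matrix(
    runif(size^2 * 3), size^2, 3
  ), H = size, W = size)
  o1 <- m$forward(panicleobb:::tape_ctx(FALSE), x, train = FALSE)
  o2 <- m2$forward(panicleobb:::tape_ctx(FALSE), x, train = FALSE)
  expect_equal(o1$p3$cls$val, o2$p3$cls$val, tolerance = 1e-12)
})
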