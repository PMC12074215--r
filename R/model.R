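#' EfficientNetV2-S style backbone specification
#'
#' The stage table of the EfficientNetV2-S feature extractor: a stride-2
#' stem convolution, three Fused-MBConv stages (a single 3x3 standard
#' convolution replacing the depthwise/expansion pair, for shallow layers)
#' and three MBConv stages with squeeze-and-excitation (ratio 0.25 of the
#' block input). The defaults reproduce the published stage table exactly
#' (channels 24/24/48/64/128/160/256, layer counts 1/2/4/4/6/9/15, strides
#' 2/1/2/2/2/1/2); the classification stage is not part of the detection
#' backbone. `width_mult` scales channels (rounded to multiples of 8) and
#' `depth_mult` scales per-stage layer counts (rounded up, at least 1).
#'
#' @param width_mult Channel width multiplier.
#' @param depth_mult Layer count multiplier.
#' @param drop_path Maximum stochastic-depth drop probability (linearly
#'   increased over block depth; 0 disables).
#' @return A list of class `backbone_spec` with the stage tibble and
#'   multipliers.
#' @export
backbone_spec <- function(width_mult = 1, depth_mult = 1, drop_path = 0) {
  stages <- tibble::tibble(
    stage = 0:6,
    operator = c(
      "conv", "fused_mbconv", "fused_mbconv", "fused_mbconv",
      "mbconv", "mbconv", "mbconv"
    ),
    expansion = c(1, 1, 4, 4, 4, 6, 6),
    channels = c(24, 24, 48, 64, 128, 160, 256),
    stride = c(2, 1, 2, 2, 2, 1, 2),
    layers = c(1, 2, 4, 4, 6, 9, 15),
    se_ratio = c(0, 0, 0, 0, 0.25, 0.25, 0.25)
  )
  stopifnot(
    width_mult > 0, depth_mult > 0, all(stages$stride %in% c(1, 2)),
    drop_path >= 0, drop_path < 1
  )
  structure(
    list(
      stages = stages, width_mult = width_mult, depth_mult = depth_mult,
      drop_path = drop_path, tap_stages = c(3, 5, 6)
    ),
    class = "backbone_spec"
  )
}

scaled_stages <- function(spec) {
  st <- spec$stages
  st$channels_scaled <- vapply(
    st$channels,
    function(c) make_divisible(c * spec$width_mult, 8), numeric(1)
  )
  st$layers_scaled <- c(1, pmax(1, ceiling(st$layers[-1] * spec$depth_mult)))
  st
}

#' Build the backbone feature extractor
#'
#' Instantiates the stages of a [backbone_spec()] and returns a model whose
#' forward pass yields the three tapped feature maps at strides 8, 16 and 32
#' (stages 3, 5 and 6). With the default spec and a 608 x 608 input the taps
#' have spatial sizes 76, 38 and 19 and channels 64, 160 and 256.
#'
#' @param spec A [backbone_spec()].
#' @param registry Optional parameter registry to attach to (used when the
#'   backbone is part of a larger model).
#' @return A list of class `obb_backbone` with the parameter registry `M`,
#'   `forward(ctx, x, train)` returning the list of taps, per-stage metadata,
#'   `tap_channels` and `tap_strides`.
#' @export
build_backbone <- function(spec = backbone_spec(), registry = NULL) {
  st <- scaled_stages(spec)
  M <- if (is.null(registry)) new_registry() else registry
  n_blocks_total <- sum(st$layers_scaled[-1])
  blk_i <- 0
  modules <- list()
  block_counts <- integer(nrow(st))
  c_prev <- 3L
  for (i in seq_len(nrow(st))) {
    row <- st[i, ]
    c_out <- row$channels_scaled
    if (row$operator == "conv") {
      modules[[i]] <- list(conv_unit(M, c_prev, c_out, 3, row$stride))
      block_counts[i] <- 1L
    } else {
      stage_mods <- vector("list", row$layers_scaled)
      for (j in seq_len(row$layers_scaled)) {
        s <- if (j == 1) row$stride else 1
        cin <- if (j == 1) c_prev else c_out
        blk_i <- blk_i + 1
        sd_p <- spec$drop_path * blk_i / max(1, n_blocks_total)
        stage_mods[[j]] <- if (row$operator == "fused_mbconv") {
          fused_mbconv(M, cin, c_out, row$expansion, s, sd_p)
        } else {
          mbconv(M, cin, c_out, row$expansion, s, row$se_ratio, sd_p)
        }
      }
      modules[[i]] <- stage_mods
      block_counts[i] <- row$layers_scaled
    }
    c_prev <- c_out
  }
  taps <- spec$tap_stages
  structure(
    list(
      M = M,
      spec = spec,
      stage_blocks = block_counts,
      tap_channels = st$channels_scaled[taps + 1],
      tap_strides = c(8L, 16L, 32L),
      forward = function(ctx, x, train = FALSE) {
        out <- list()
        for (i in seq_along(modules)) {
          for (m in modules[[i]]) x <- m$forward(ctx, x, train)
          if ((i - 1) %in% taps) out[[length(out) + 1]] <- x
        }
        names(out) <- c("p3", "p4", "p5")
        out
      }
    ),
    class = "obb_backbone"
  )
}

#' Detector configuration
#'
#' Hyperparameters of the assembled oriented detector: backbone width/depth
#' multipliers, the number K of parallel kernels per dynamic convolution,
#' which of the three detection branches (strides 8/16/32, i.e. 76x76 /
#' 38x38 / 19x19 feature maps on a 608 input) use the dynamic-convolution
#' block, the number of classes, and the box-regression mode. The default
#' multipliers (width 0.35, depth 0.625) are the package's calibrated
#' lightweight scale, chosen so the default detector has about 2.45 M
#' trainable parameters.
#'
#' @param width_mult,depth_mult Backbone and neck scaling multipliers.
#' @param nc Number of classes.
#' @param reg_max Number of bins of the discretized box-side distributions
#'   (decoded by expectation) when `box_mode = "dfl"`.
#' @param K Parallel kernels per dynamic convolution.
#' @param head_dconv Logical length-3 vector: use C3k2_DConv in the stride
#'   8 / 16 / 32 branches.
#' @param box_mode `"dfl"` (discretized distributions) or `"direct"`
#'   (direct offset regression).
#' @param temperature Initial softmax temperature of the dynamic-conv gates
#'   (annealed toward 1 during training).
#' @param drop_path Maximum stochastic-depth rate in the backbone.
#' @param w_box,w_cls Loss weights for the box and classification terms.
#' @return A list of class `model_config`.
#' @export
model_config <- function(width_mult = 0.35, depth_mult = 0.625, nc = 1L,
                         reg_max = 16L, K = 4L,
                         head_dconv = c(TRUE, TRUE, TRUE),
                         box_mode = c("dfl", "direct"),
                         temperature = 30, drop_path = 0,
                         w_box = 7.5, w_cls = 0.5) {
  box_mode <- match.arg(box_mode)
  if (length(head_dconv) != 3 || !is.logical(head_dconv)) {
    rlang::abort("head_dconv must be 3 logical flags (strides 8/16/32)",
      class = "panicleobb_config_error"
    )
  }
  stopifnot(K >= 2, reg_max >= 1, nc >= 1, temperature > 0)
  structure(
    list(
      width_mult = width_mult, depth_mult = depth_mult, nc = as.integer(nc),
      reg_max = as.integer(reg_max), K = as.integer(K),
      head_dconv = head_dconv, box_mode = box_mode,
      temperature = temperature, drop_path = drop_path,
      w_box = w_box, w_cls = w_cls
    ),
    class = "model_config"
  )
}

#' Assemble the oriented detector
#'
#' Builds the full detector: the scaled backbone, a PAN-style neck (SPPF and
#' position-sensitive attention on the deepest tap, top-down and bottom-up
#' fusion with nearest upsampling and concatenation), and three decoupled
#' detection branches at strides 8/16/32, each emitting per-location class
#' logits, box regression channels and one angle channel (sigmoid-mapped to
#' `[-pi/2, pi/2)`). C3k2 blocks in the three head branches are replaced by
#' dynamic-convolution variants where `cfg$head_dconv` flags them.
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `oe_yolo`.
#' @export
build_oe_yolo <- function(cfg = model_config(), seed = 0L) {
  with_seed(seed, {
    M <- new_registry()
    temp <- new_buffer(M, cfg$temperature)
    bspec <- backbone_spec(cfg$width_mult, cfg$depth_mult, cfg$drop_path)
    backbone <- build_backbone(bspec, registry = M)
    ch <- backbone$tap_channels # c3, c4, c5
    n_rep <- max(1, round(2 * cfg$depth_mult))
    sppf <- sppf_unit(M, ch[3], ch[3])
    psa <- c2psa_unit(M, ch[3], n = n_rep)
    td4 <- c3k2_unit(M, ch[3] + ch[2], ch[2], n_rep)
    td3 <- c3k2_unit(M, ch[2] + ch[1], ch[1], n_rep,
      dconv = cfg$head_dconv[1], K = cfg$K, temp = temp
    )
    down3 <- conv_unit(M, ch[1], ch[1], 3, 2)
    bu4 <- c3k2_unit(M, ch[1] + ch[2], ch[2], n_rep,
      dconv = cfg$head_dconv[2], K = cfg$K, temp = temp
    )
    down4 <- conv_unit(M, ch[2], ch[2], 3, 2)
    bu5 <- c3k2_unit(M, ch[2] + ch[3], ch[3], n_rep,
      dconv = cfg$head_dconv[3], K = cfg$K, temp = temp
    )
    direct <- cfg$box_mode == "direct"
    heads <- list(
      detect_branch(M, ch[1], cfg$nc, cfg$reg_max, direct),
      detect_branch(M, ch[2], cfg$nc, cfg$reg_max, direct),
      detect_branch(M, ch[3], cfg$nc, cfg$reg_max, direct)
    )
    forward <- function(ctx, x, train = FALSE) {
      taps <- backbone$forward(ctx, x, train)
      p5 <- psa$forward(ctx, sppf$forward(ctx, taps$p5, train), train)
      x4t <- td4$forward(
        ctx, op_concat(ctx, list(op_upsample2(ctx, p5), taps$p4)), train
      )
      x3 <- td3$forward(
        ctx, op_concat(ctx, list(op_upsample2(ctx, x4t), taps$p3)), train
      )
      x4 <- bu4$forward(
        ctx, op_concat(ctx, list(down3$forward(ctx, x3, train), x4t)), train
      )
      x5 <- bu5$forward(
        ctx, op_concat(ctx, list(down4$forward(ctx, x4, train), p5)), train
      )
      list(
        p3 = heads[[1]]$forward(ctx, x3, train),
        p4 = heads[[2]]$forward(ctx, x4, train),
        p5 = heads[[3]]$forward(ctx, x5, train)
      )
    }
    structure(
      list(
        M = M, cfg = cfg, temp = temp, backbone = backbone,
        strides = c(8L, 16L, 32L), forward = forward
      ),
      class = "oe_yolo"
    )
  })
}

#' Parameter and FLOP accounting
#'
#' Counts trainable scalars and, when `input_size` is given, the floating
#' point operations of one forward pass at that input size (one
#' multiply-accumulate counted as 2 FLOPs over convolutions and linear
#' maps).
#'
#' @param model An `oe_yolo` or `obb_backbone` model.
#' @param input_size Optional square input size for the FLOP count.
#' @return A list with `params` and (if requested) `flops`.
#' @export
model_complexity <- function(model, input_size = NULL) {
  params <- sum(vapply(model$M$params, function(p) length(p$val), numeric(1)))
  out <- list(params = params)
  if (!is.null(input_size)) {
    ctx <- tape_ctx(track = FALSE)
    x <- list(
      id = NA_integer_,
      val = matrix(0, input_size^2, 3), H = input_size, W = input_size
    )
    model$forward(ctx, x, train = FALSE)
    out$flops <- ctx$flops
  }
  out
}

#' @export
print.oe_yolo <- function(x, ...) {
  cc <- model_complexity(x)
  cat(
    "<oe_yolo> width ", x$cfg$width_mult, ", depth ", x$cfg$depth_mult,
    ", ", x$cfg$box_mode, " box head, dconv ",
    paste(ifelse(x$cfg$head_dconv, "y", "n"), collapse = "/"),
    "; ", format(round(cc$params / 1e6, 2), nsmall = 2), "M parameters\n",
    sep = ""
  )
  invisible(x)
}

img_to_tensor <- function(image) {
  d <- dim(image)
  # H x W x 3 arrays flatten directly to the (H*W) x 3 layout
  list(
    id = NA_integer_,
    val = matrix(image, d[1] * d[2], 3),
    H = d[1], W = d[2]
  )
}

#' Save / load detector checkpoints
#'
#' The checkpoint holds the configuration, all parameter values and buffers
#' (running statistics, gate temperature); a JSON sidecar records the
#' configuration for inspection.
#'
#' @param model An `oe_yolo` model.
#' @param path Checkpoint file path (`.rds`).
#' @return `load_model()` returns the restored `oe_yolo` model.
#' @export
save_model <- function(model, path) {
  saveRDS(
    list(
      cfg = unclass(model$cfg),
      params = lapply(model$M$params, function(p) p$val),
      buffers = lapply(model$M$buffers, function(b) b$val)
    ),
    path
  )
  jsonlite::write_json(unclass(model$cfg), paste0(path, ".json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(model_config, ck$cfg[setdiff(
    names(ck$cfg),
    character(0)
  )])
  model <- build_oe_yolo(cfg)
  stopifnot(length(model$M$params) == length(ck$params))
  for (i in seq_along(ck$params)) model$M$params[[i]]$val <- ck$params[[i]]
  for (i in seq_along(ck$buffers)) model$M$buffers[[i]]$val <- ck$buffers[[i]]
  model
}
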