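# Decoding of raw head outputs to oriented boxes, and the gradient chain
# back to the raw channels. Grid cell (row i, col j) at stride s has center
# ((j + 0.5) s, (i + 0.5) s); spatial index is s0 = i + H * j (0-based).

sigmoid <- function(x) 1 / (1 + exp(-x))

# box_val: S x (4 or 4*reg_max); ang_val: S x 1; sel: 1-based spatial subset
decode_raw <- function(box_val, ang_val, stride, H, W, mode, reg_max,
                       sel = NULL) {
  if (is.null(sel)) sel <- seq_len(H * W)
  s0 <- sel - 1
  ii <- s0 %% H
  jj <- s0 %/% H
  ta <- ang_val[sel, 1]
  sa <- sigmoid(ta)
  theta <- (sa - 0.5) * pi
  if (mode == "direct") {
    tx <- box_val[sel, 1]
    ty <- box_val[sel, 2]
    tw <- pmin(box_val[sel, 3], 5)
    th <- pmin(box_val[sel, 4], 5)
    sx <- sigmoid(tx)
    sy <- sigmoid(ty)
    w <- stride * exp(tw)
    h <- stride * exp(th)
    out <- list(
      cx = (jj + 2 * sx - 0.5) * stride,
      cy = (ii + 2 * sy - 0.5) * stride,
      w = w, h = h, theta = theta,
      cache = list(
        mode = mode, stride = stride, sel = sel, sx = sx, sy = sy,
        sa = sa, w = w, h = h,
        free_w = box_val[sel, 3] <= 5, free_h = box_val[sel, 4] <= 5
      )
    )
  } else {
    n <- length(sel)
    probs <- vector("list", 4)
    dist <- matrix(0, n, 4) # l, t, r, b in stride units
    bins <- 0:(reg_max - 1)
    for (g in 1:4) {
      z <- box_val[sel, ((g - 1) * reg_max + 1):(g * reg_max), drop = FALSE]
      z <- z - apply(z, 1, max) # n x reg_max
      e <- exp(z)
      p <- e / rowSums(e)
      probs[[g]] <- p
      dist[, g] <- as.numeric(p %*% bins)
    }
    ox <- (dist[, 3] - dist[, 1]) / 2
    oy <- (dist[, 4] - dist[, 2]) / 2
    ct <- cos(theta)
    st <- sin(theta)
    out <- list(
      cx = (jj + 0.5) * stride + (ox * ct - oy * st) * stride,
      cy = (ii + 0.5) * stride + (ox * st + oy * ct) * stride,
      w = pmax(dist[, 1] + dist[, 3], 1e-2) * stride,
      h = pmax(dist[, 2] + dist[, 4], 1e-2) * stride,
      theta = theta,
      cache = list(
        mode = mode, stride = stride, sel = sel, probs = probs, dist = dist,
        ox = ox, oy = oy, ct = ct, st = st, sa = sa, reg_max = reg_max
      )
    )
  }
  out
}

# chain dL/d(cx,cy,w,h,theta) (n x 5 matrix) back to raw box/angle channels;
# returns matrices aligned with cache$sel
decode_grads <- function(G, cache) {
  s <- cache$stride
  if (cache$mode == "direct") {
    dbox <- cbind(
      G[, 1] * 2 * cache$sx * (1 - cache$sx) * s,
      G[, 2] * 2 * cache$sy * (1 - cache$sy) * s,
      G[, 3] * cache$w * cache$free_w, # w = s exp(tw): dw/dtw = w
      G[, 4] * cache$h * cache$free_h
    )
    dang <- G[, 5] * pi * cache$sa * (1 - cache$sa)
    list(dbox = dbox, dang = dang)
  } else {
    ct <- cache$ct
    st <- cache$st
    # d(cx,cy,w,h) / d(l,t,r,b) in stride units
    dl <- G[, 1] * (-ct / 2) * s + G[, 2] * (-st / 2) * s + G[, 3] * s
    dt <- G[, 1] * (st / 2) * s + G[, 2] * (-ct / 2) * s + G[, 4] * s
    dr <- G[, 1] * (ct / 2) * s + G[, 2] * (st / 2) * s + G[, 3] * s
    db <- G[, 1] * (-st / 2) * s + G[, 2] * (ct / 2) * s + G[, 4] * s
    ddist <- cbind(dl, dt, dr, db)
    reg_max <- cache$reg_max
    bins <- 0:(reg_max - 1)
    n <- nrow(G)
    dbox <- matrix(0, n, 4 * reg_max)
    for (g in 1:4) {
      p <- cache$probs[[g]] # n x reg_max
      d <- cache$dist[, g]
      # d dist / d z_k = p_k (k - dist)
      dz <- p * (matrix(bins, n, reg_max, byrow = TRUE) - d)
      dbox[, ((g - 1) * reg_max + 1):(g * reg_max)] <- dz * ddist[, g]
    }
    # theta also moves the center through the rotated offsets
    dtheta <- G[, 5] +
      G[, 1] * (-cache$ox * st - cache$oy * ct) * s +
      G[, 2] * (cache$ox * ct - cache$oy * st) * s
    dang <- dtheta * pi * cache$sa * (1 - cache$sa)
    list(dbox = dbox, dang = dang)
  }
}

# central finite differences of (1 - prob_iou) wrt the five box parameters;
# prob_iou's closed form is smooth, so short steps are accurate and the cost
# is ten vectorized evaluations
probiou_loss_grad <- function(pred, gt) {
  n <- nrow(pred)
  P <- cbind(pred$cx, pred$cy, pred$w, pred$h, pred$theta)
  gx <- gt$cx
  gy <- gt$cy
  gw <- gt$w
  gh <- gt$h
  gth <- gt$theta
  eval_p <- function(M) {
    prob_iou_par(M[, 1], M[, 2], M[, 3], M[, 4], M[, 5], gx, gy, gw, gh, gth)
  }
  eps <- cbind(
    rep(0.05, n), rep(0.05, n),
    pmax(0.01 * P[, 3], 0.02), pmax(0.01 * P[, 4], 0.02), rep(0.002, n)
  )
  G <- matrix(0, n, 5)
  for (p in 1:5) {
    hi <- P
    lo <- P
    hi[, p] <- hi[, p] + eps[, p]
    lo[, p] <- if (p %in% 3:4) pmax(lo[, p] - eps[, p], 1e-3) else lo[, p] - eps[, p]
    G[, p] <- -(eval_p(hi) - eval_p(lo)) / (hi[, p] - lo[, p])
  }
  list(loss = 1 - eval_p(P), grad = G)
}

#' Assign candidate boxes to ground truths by the IoU rule
#'
#' A candidate is positive when its best polygon IoU over the ground truths
#' reaches `pos_thr` (default 0.7); it is matched to the argmax ground truth
#' (ties to the lower index). All other candidates are negative.
#'
#' @param candidates,gts Data frames of oriented boxes.
#' @param pos_thr Positive-assignment IoU threshold in (0, 1].
#' @return A tibble with one row per candidate: `positive` flag,
#'   `matched_gt` index (NA for negatives) and the best `iou`.
#' @export
assign_targets <- function(candidates, gts, pos_thr = 0.7) {
  stopifnot(pos_thr > 0, pos_thr <= 1)
  n <- nrow(candidates)
  if (n == 0 || nrow(gts) == 0) {
    return(tibble::tibble(
      positive = logical(n), matched_gt = rep(NA_integer_, n),
      iou = numeric(n)
    ))
  }
  iou <- matrix(0, n, nrow(gts))
  for (g in seq_len(nrow(gts))) {
    iou[, g] <- polygon_iou(candidates, gts[g, ])
  }
  best <- apply(iou, 1, which.max)
  best_iou <- iou[cbind(seq_len(n), best)]
  pos <- best_iou >= pos_thr
  tibble::tibble(
    positive = pos,
    matched_gt = ifelse(pos, best, NA_integer_),
    iou = best_iou
  )
}

#' Composite detection loss
#'
#' `box_term` is the mean over positive candidates of `1 - prob_iou` between
#' the predicted box and its matched ground truth (0 when there are no
#' positives); `cls_term` is the binary cross-entropy of the predicted scores
#' against the positive/negative flags over all locations. The total is
#' `w_box * box_term + w_cls * cls_term`: non-negative, and zero exactly when
#' every positive predicts its ground truth exactly and classification is
#' perfect.
#'
#' @param predictions A data frame with box columns and a `score` column of
#'   probabilities.
#' @param assignment The result of [assign_targets()] for these predictions.
#' @param gts Ground-truth boxes.
#' @param w_box,w_cls Loss weights.
#' @return A list with `total`, `box_term`, `cls_term`.
#' @export
detection_loss <- function(predictions, assignment, gts, w_box = 7.5,
                           w_cls = 0.5) {
  eps <- 1e-12
  pos <- which(assignment$positive)
  box_term <- if (length(pos) > 0) {
    mean(1 - prob_iou(
      predictions[pos, ],
      gts[assignment$matched_gt[pos], ]
    ))
  } else {
    0
  }
  y <- as.numeric(assignment$positive)
  p <- pmin(pmax(predictions$score, eps), 1 - eps)
  bce <- -(y * log(p) + (1 - y) * log(1 - p))
  bce[y == 1 & predictions$score >= 1 - eps] <- 0
  bce[y == 0 & predictions$score <= eps] <- 0
  cls_term <- mean(bce)
  list(
    total = w_box * box_term + w_cls * cls_term,
    box_term = box_term, cls_term = cls_term
  )
}

# Trainer-side assignment: grid cells whose center lies inside a ground
# truth AND within 1.25 strides of its center become positives (capped at
# the `max_pos` nearest; the nearest cell is always included); conflicts go
# to the nearer ground truth. The center-proximity restriction matters for
# slender boxes: the head's center offset reaches at most 1.5 cells, so
# cells far along the main axis could never regress the true center.
assign_training_targets <- function(gts, strides, dims, max_pos = 4) {
  out <- list()
  if (nrow(gts) == 0) {
    return(out)
  }
  # slender objects need fine resolution across their thin dimension, so
  # the level split favors the stride-8 map
  lev_of <- function(w) if (w < 128) 1L else if (w < 256) 2L else 3L
  claims <- list()
  for (g in seq_len(nrow(gts))) {
    lev <- lev_of(gts$w[g])
    s <- strides[lev]
    H <- dims[[lev]][1]
    W <- dims[[lev]][2]
    clamp_rng <- function(lo, hi, n) {
      seq(max(0, min(n - 1, lo)), min(n - 1, max(0, hi)))
    }
    jr <- clamp_rng(
      floor((gts$cx[g] - gts$w[g] / 2) / s),
      ceiling((gts$cx[g] + gts$w[g] / 2) / s), W
    )
    ir <- clamp_rng(
      floor((gts$cy[g] - gts$w[g] / 2) / s),
      ceiling((gts$cy[g] + gts$w[g] / 2) / s), H
    )
    jj <- rep(jr, each = length(ir))
    ii <- rep(ir, times = length(jr))
    px <- (jj + 0.5) * s
    py <- (ii + 0.5) * s
    ct <- cos(gts$theta[g])
    st <- sin(gts$theta[g])
    u <- (px - gts$cx[g]) * ct + (py - gts$cy[g]) * st
    v <- -(px - gts$cx[g]) * st + (py - gts$cy[g]) * ct
    inside <- abs(u) <= gts$w[g] / 2 & abs(v) <= gts$h[g] / 2
    d2 <- (px - gts$cx[g])^2 + (py - gts$cy[g])^2
    idx <- which(inside & d2 <= s^2)
    if (length(idx) > max_pos) idx <- idx[order(d2[idx])][seq_len(max_pos)]
    if (length(idx) == 0) idx <- which.min(d2)
    claims[[g]] <- cbind(
      level = lev, cell = ii[idx] + H * jj[idx] + 1,
      gt = g, d2 = d2[idx]
    )
  }
  cl <- do.call(rbind, claims)
  cl <- cl[order(cl[, "level"], cl[, "cell"], cl[, "d2"]), , drop = FALSE]
  cl <- cl[!duplicated(cl[, c("level", "cell"), drop = FALSE]), , drop = FALSE]
  lapply(
    split(seq_len(nrow(cl)), cl[, "level"]),
    function(r) list(cell = cl[r, "cell"], gt = cl[r, "gt"])
  )
}

#' Training configuration
#'
#' Defaults follow the detector's reference schedule: 110 epochs, SGD with
#' initial learning rate 0.01 decayed by cosine annealing to `lr0/100`,
#' momentum 0.937, L2 weight decay 0.001, 608 px inputs and positive
#' assignment at IoU 0.7.
#'
#' @param epochs Number of epochs.
#' @param lr0 Initial learning rate.
#' @param weight_decay L2 regularization coefficient.
#' @param image_size Square input size (multiple of 32).
#' @param batch_size Images per optimizer step (gradients are accumulated).
#' @param momentum SGD momentum.
#' @param seed Master seed governing data order, augmentation and weight
#'   init.
#' @param assignment_iou_pos Positive-assignment IoU threshold.
#' @param w_box,w_cls Loss weights.
#' @param augmentation An [augmentation_spec()] or `NULL` to disable.
#' @param crop_size Optional square random-crop side (multiple of 32) taken
#'   from each training image per iteration; preserves object scale while
#'   reducing per-iteration cost. `NULL` trains on full images.
#' @param min_lr_frac Final learning rate as a fraction of `lr0`.
#' @param ema_decay Decay of the exponential moving average of the weights
#'   kept alongside SGD; the averaged weights are installed in the returned
#'   model (they smooth out late-schedule gradient noise). `NULL` disables.
#' @param val_interval Epoch interval of validation mAP evaluation (the
#'   final epoch is always evaluated).
#' @param conf_thr,nms_iou Default detection thresholds (counting,
#'   deployment).
#' @param val_conf_thr Low score cut used when computing validation mAP;
#'   average precision integrates the full precision-recall curve, so
#'   validation keeps low-confidence detections that deployment discards.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 110, lr0 = 0.01, weight_decay = 0.001,
                         image_size = 608, batch_size = 16,
                         momentum = 0.937, seed = 0L,
                         assignment_iou_pos = 0.7, w_box = 7.5, w_cls = 0.5,
                         augmentation = NULL, crop_size = NULL,
                         min_lr_frac = 0.01, ema_decay = 0.99,
                         val_interval = 1, conf_thr = 0.25, nms_iou = 0.35,
                         val_conf_thr = 0.01) {
  stopifnot(epochs >= 1, lr0 > 0, image_size %% 32 == 0,
    assignment_iou_pos > 0, assignment_iou_pos <= 1,
    is.null(crop_size) || crop_size %% 32 == 0)
  structure(
    list(
      epochs = as.integer(epochs), lr0 = lr0, weight_decay = weight_decay,
      image_size = as.integer(image_size), batch_size = as.integer(batch_size),
      momentum = momentum, seed = as.integer(seed),
      assignment_iou_pos = assignment_iou_pos, w_box = w_box, w_cls = w_cls,
      augmentation = augmentation, crop_size = crop_size,
      min_lr_frac = min_lr_frac, ema_decay = ema_decay,
      val_interval = as.integer(val_interval), conf_thr = conf_thr,
      nms_iou = nms_iou, val_conf_thr = val_conf_thr
    ),
    class = "train_config"
  )
}

#' Cosine-annealed learning rate
#'
#' `lr(0) = lr0` and `lr(epochs - 1) = lr0 * min_lr_frac`, interpolated by a
#' half cosine.
#'
#' @param epoch 0-based epoch index.
#' @param epochs Total epochs.
#' @param lr0 Initial learning rate.
#' @param min_lr_frac Final fraction of `lr0`.
#' @return The learning rate for that epoch.
#' @export
cosine_lr <- function(epoch, epochs, lr0, min_lr_frac = 0.01) {
  if (epochs == 1) {
    return(lr0)
  }
  min_lr <- lr0 * min_lr_frac
  min_lr + 0.5 * (lr0 - min_lr) * (1 + cos(pi * epoch / (epochs - 1)))
}

sgd_step <- function(M, lr, momentum, weight_decay, n_accum,
                     ema_decay = NULL) {
  for (p in M$params) {
    if (is.null(p$grad)) next
    g <- p$grad / n_accum
    if (p$decay) g <- g + weight_decay * p$val
    if (is.null(p$mom)) p$mom <- g else p$mom <- momentum * p$mom + g
    p$val <- p$val - lr * p$mom
    p$grad <- NULL
    if (!is.null(ema_decay)) {
      if (is.null(p$ema)) {
        p$ema <- p$val
      } else {
        p$ema <- ema_decay * p$ema + (1 - ema_decay) * p$val
      }
    }
  }
  invisible(NULL)
}

# loss + gradients wrt the raw head outputs for one image
image_loss_grads <- function(outs, gts, cfg_model, strides, w_box, w_cls,
                             pos_thr) {
  dims <- lapply(outs, function(o) c(o$box$H, o$box$W))
  assigned <- assign_training_targets(gts, strides, dims)
  npos <- sum(vapply(assigned, function(a) length(a$cell), integer(1)))
  grads <- list()
  box_loss_sum <- 0
  cls_loss_sum <- 0
  n_loc <- 0
  for (lev in 1:3) {
    o <- outs[[lev]]
    H <- o$box$H
    W <- o$box$W
    S <- H * W
    n_loc <- n_loc + S
    y <- numeric(S)
    dbox <- matrix(0, S, ncol(o$box$val))
    dang <- matrix(0, S, 1)
    key <- as.character(lev)
    if (!is.null(assigned[[key]]) && length(assigned[[key]]$cell) > 0) {
      a <- assigned[[key]]
      dec <- decode_raw(
        o$box$val, o$ang$val, strides[lev], H, W,
        cfg_model$box_mode, cfg_model$reg_max, sel = a$cell
      )
      pred <- tibble::tibble(
        cx = dec$cx, cy = dec$cy, w = dec$w, h = dec$h, theta = dec$theta
      )
      pg <- probiou_loss_grad(pred, gts[a$gt, ])
      box_loss_sum <- box_loss_sum + sum(pg$loss)
      dg <- decode_grads(pg$grad * (w_box / max(1, npos)), dec$cache)
      dbox[a$cell, ] <- dbox[a$cell, ] + dg$dbox
      dang[a$cell, 1] <- dang[a$cell, 1] + dg$dang
      # IoU-aware soft targets: the score learns to rank localization
      # quality, which sharpens NMS and the precision-recall ordering
      y[a$cell] <- pmin(pmax(1 - pg$loss, 0.05), 1)
    }
    p <- sigmoid(o$cls$val[, 1])
    pe <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    cls_loss_sum <- cls_loss_sum + sum(-(y * log(pe) + (1 - y) * log(1 - pe)))
    dcls <- matrix((p - y) * (w_cls / max(1, npos)), S, 1)
    grads[[lev]] <- list(box = dbox, cls = dcls, ang = dang)
  }
  box_term <- box_loss_sum / max(1, npos)
  cls_term <- cls_loss_sum / max(1, npos)
  list(
    total = w_box * box_term + w_cls * cls_term,
    box_term = box_term, cls_term = cls_term, npos = npos, grads = grads
  )
}

#' Train the oriented detector
#'
#' Stochastic gradient descent with momentum over a dataset directory in the
#' standard layout (see [generate_dataset()]): per image, the forward pass
#' runs on the autodiff tape, the composite loss (ProbIoU box term over
#' positives + binary cross-entropy over all locations) supplies cotangents
#' at the three head outputs, and backpropagation accumulates parameter
#' gradients; an optimizer step is taken every `batch_size` images. The
#' learning rate follows cosine annealing and the dynamic-convolution gate
#' temperature is annealed linearly from its initial value to 1 over the
#' first 10 epochs. One seed governs data order, augmentation and (via
#' [build_oe_yolo()]) weight initialization.
#'
#' @param model An `oe_yolo` model.
#' @param data_dir Dataset directory with `images/` and `labels/` splits.
#' @param cfg A [train_config()].
#' @param quiet Suppress per-epoch progress messages.
#' @return An object of class `obb_training`: list with the trained `model`
#'   and a per-epoch `log` tibble (losses, learning rate, validation mAP50
#'   where evaluated).
#' @export
train_detector <- function(model, data_dir, cfg = train_config(),
                           quiet = FALSE) {
  files <- load_dataset(data_dir, "train")
  if (nrow(files) == 0) {
    rlang::abort("no training images found", class = "panicleobb_data_error")
  }
  val_files <- load_dataset(data_dir, "val")
  temp0 <- model$temp$val
  log_rows <- list()
  # decode images once (8-bit planes) and parse labels once; a raw cache of
  # a few hundred tiles costs ~1 MB per megapixel instead of 24
  cache <- lapply(seq_len(nrow(files)), function(fi) {
    img <- png::readPNG(files$image[fi])
    if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
    img <- img[, , 1:3, drop = FALSE]
    list(
      raw = as.raw(round(pmin(pmax(img, 0), 1) * 255)),
      dim = dim(img),
      ann = parse_yolo_obb(
        readLines(files$label[fi]), dim(img)[2], dim(img)[1]
      )
    )
  })
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs) - 1L) {
      lr <- cosine_lr(epoch, cfg$epochs, cfg$lr0, cfg$min_lr_frac)
      model$temp$val <- max(1, temp0 - (temp0 - 1) * epoch / 10)
      ord <- sample(nrow(files))
      tot <- 0
      box_t <- 0
      cls_t <- 0
      n_acc <- 0
      for (fi in ord) {
        entry <- cache[[fi]]
        ann <- entry$ann
        raw_arr <- array(entry$raw, entry$dim)
        if (!is.null(cfg$augmentation)) {
          img <- array(as.integer(raw_arr), entry$dim) / 255
          aug <- augment_scene(img, ann, cfg$augmentation,
            seed = sample.int(.Machine$integer.max - 1L, 1)
          )
          img <- aug$image
          ann <- aug$annotations
        } else {
          img <- NULL
        }
        cs <- cfg$crop_size
        if (!is.null(cs) && cs < min(entry$dim[1:2])) {
          x0 <- sample.int(entry$dim[2] - cs + 1, 1) - 1
          y0 <- sample.int(entry$dim[1] - cs + 1, 1) - 1
          img <- if (is.null(img)) {
            # convert only the cropped window from the 8-bit cache
            array(as.integer(
              raw_arr[(y0 + 1):(y0 + cs), (x0 + 1):(x0 + cs), , drop = FALSE]
            ), c(cs, cs, 3)) / 255
          } else {
            img[(y0 + 1):(y0 + cs), (x0 + 1):(x0 + cs), , drop = FALSE]
          }
          keep <- ann$cx >= x0 & ann$cx < x0 + cs &
            ann$cy >= y0 & ann$cy < y0 + cs
          ann <- ann[keep, ]
          ann$cx <- ann$cx - x0
          ann$cy <- ann$cy - y0
        } else if (is.null(img)) {
          img <- array(as.integer(raw_arr), entry$dim) / 255
        }
        ctx <- tape_ctx(track = TRUE)
        outs <- model$forward(ctx, img_to_tensor(img), train = TRUE)
        lg <- image_loss_grads(
          outs, ann, model$cfg, model$strides,
          cfg$w_box, cfg$w_cls, cfg$assignment_iou_pos
        )
        if (!is.finite(lg$total)) {
          rlang::abort(
            paste0(
              "non-finite loss at epoch ", epoch, " image ",
              basename(files$image[fi])
            ),
            class = "panicleobb_nan_loss"
          )
        }
        roots <- list()
        for (lev in 1:3) {
          roots <- c(roots, list(
            list(id = outs[[lev]]$box$id, grad = lg$grads[[lev]]$box),
            list(id = outs[[lev]]$cls$id, grad = lg$grads[[lev]]$cls),
            list(id = outs[[lev]]$ang$id, grad = lg$grads[[lev]]$ang)
          ))
        }
        tape_backward(ctx, roots)
        rm(ctx)
        tot <- tot + lg$total
        box_t <- box_t + lg$box_term
        cls_t <- cls_t + lg$cls_term
        n_acc <- n_acc + 1
        if (n_acc %% cfg$batch_size == 0 || fi == ord[length(ord)]) {
          sgd_step(
            model$M, lr, cfg$momentum, cfg$weight_decay,
            ((n_acc - 1) %% cfg$batch_size) + 1, cfg$ema_decay
          )
        }
      }
      final_epoch <- epoch == cfg$epochs - 1
      if (final_epoch && !is.null(cfg$ema_decay)) {
        # install the averaged weights for the final model
        for (p in model$M$params) {
          if (!is.null(p$ema)) p$val <- p$ema
        }
      }
      map50 <- NA_real_
      if (nrow(val_files) > 0 &&
        (epoch %% cfg$val_interval == 0 || final_epoch)) {
        map50 <- validate_map50(model, val_files, cfg)
      }
      log_rows[[epoch + 1]] <- tibble::tibble(
        epoch = epoch, lr = lr, loss = tot / nrow(files),
        box_loss = box_t / nrow(files), cls_loss = cls_t / nrow(files),
        val_map50 = map50
      )
      if (!quiet) {
        message(sprintf(
          "epoch %3d  lr %.5f  loss %.4f (box %.4f cls %.4f)  mAP50 %s",
          epoch, lr, tot / nrow(files), box_t / nrow(files),
          cls_t / nrow(files), ifelse(is.na(map50), "-", sprintf("%.3f", map50))
        ))
      }
    }
  })
  structure(
    list(model = model, log = dplyr::bind_rows(log_rows), cfg = cfg),
    class = "obb_training"
  )
}

validate_map50 <- function(model, val_files, cfg) {
  dets <- list()
  gts <- list()
  for (i in seq_len(nrow(val_files))) {
    img <- png::readPNG(val_files$image[i])
    if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
    img <- img[, , 1:3, drop = FALSE]
    dets[[i]] <- detect(model, img,
      conf_thr = cfg$val_conf_thr,
      nms_iou = cfg$nms_iou
    )
    gts[[i]] <- parse_yolo_obb(
      readLines(val_files$label[i]),
      dim(img)[2], dim(img)[1]
    )
  }
  mean_ap(dets, gts, thresholds = 0.5)$map[1]
}

#' Run inference on an image
#'
#' Forward pass in evaluation mode (stochastic depth disabled, running batch
#' statistics), decoding of every grid location to an oriented box with a
#' confidence score, score filtering and rotated non-maximum suppression at
#' `nms_iou` (default 0.35).
#'
#' @param model An `oe_yolo` model.
#' @param image An `H x W x 3` array in \[0, 1\] (at least 32 x 32, sides
#'   multiples of 32).
#' @param conf_thr Minimum confidence score.
#' @param nms_iou NMS suppression threshold.
#' @return A detection tibble: box columns, `score`, `class_id`.
#' @export
detect <- function(model, image, conf_thr = 0.25, nms_iou = 0.35) {
  d <- dim(image)
  if (is.null(d) || d[1] < 32 || d[2] < 32) {
    rlang::abort("image must be at least 32 x 32",
      class = "panicleobb_invalid_image"
    )
  }
  ctx <- tape_ctx(track = FALSE)
  outs <- model$forward(ctx, img_to_tensor(image), train = FALSE)
  rows <- list()
  for (lev in 1:3) {
    o <- outs[[lev]]
    dec <- decode_raw(
      o$box$val, o$ang$val, model$strides[lev], o$box$H, o$box$W,
      model$cfg$box_mode, model$cfg$reg_max
    )
    scores <- sigmoid(o$cls$val) # S x nc
    best <- if (ncol(scores) == 1) {
      list(score = scores[, 1], cls = rep(0L, nrow(scores)))
    } else {
      list(
        score = apply(scores, 1, max),
        cls = as.integer(max.col(scores) - 1L)
      )
    }
    keep <- which(best$score >= conf_thr)
    if (length(keep) == 0) next
    rows[[lev]] <- tibble::tibble(
      cx = dec$cx[keep], cy = dec$cy[keep], w = dec$w[keep],
      h = dec$h[keep], theta = dec$theta[keep],
      score = best$score[keep], class_id = best$cls[keep]
    )
  }
  if (length(rows) == 0) {
    return(tibble::tibble(
      cx = double(0), cy = double(0), w = double(0), h = double(0),
      theta = double(0), score = double(0), class_id = integer(0)
    ))
  }
  dets <- canonicalize_obb(dplyr::bind_rows(rows))
  rotated_nms(dets, nms_iou)
}
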