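test_that("IoU-rule target assignment follows the 0.7 threshold", {
  gts <- dplyr::bind_rows(obb(50, 50, 40, 10, 0.2), obb(150, 150, 60, 12, -0.5))
  # identical candidate: IoU 1 -> positive, matched to its twin
  # shifted candidate engineered to overlap above/below the threshold
  near <- obb(52, 50, 40, 10, 0.2)
  far <- obb(70, 60, 40, 10, 1.2)
  cands <- dplyr::bind_rows(gts[1, ], near, far)
  iou_near <- polygon_iou(near, gts[1, ])
  expect_gt(iou_near, 0.7) # fixture sanity
  iou_far <- max(polygon_iou(far, gts[1, ]), polygon_iou(far, gts[2, ]))
  expect_lt(iou_far, 0.7)

  a <- assign_targets(cands, gts, pos_thr = 0.7)
  expect_equal(a$positive, c(TRUE, TRUE, FALSE))
  expect_equal(a$matched_gt, c(1L, 1L, NA_integer_))

  none <- assign_targets(cands, gts[0, ], 0.7)
  expect_true(all(!none$positive))
})

test_that("detection loss is zero exactly at the perfect fixed point", {
  gts <- dplyr::bind_rows(obb(50, 50, 40, 10, 0.2), obb(150, 150, 60, 12, -0.5))
  perfect <- gts
  perfect$score <- 1
  a <- assign_targets(perfect, gts, 0.7)
  l <- detection_loss(perfect, a, gts)
  expect_equal(l$total, 0)
  expect_equal(l$box_term, 0)

  # far predictions: box term approaches 1 per positive
  off <- gts
  off$cx <- off$cx + 1e5
  off$score <- 1
  a2 <- tibble::tibble(positive = c(TRUE, TRUE), matched_gt = c(1L, 2L),
    iou = 0)
  l2 <- detection_loss(off, a2, gts)
  expect_equal(l2$box_term, 1, tolerance = 1e-6)

  # doubling w_box doubles the box contribution
  mid <- gts
  mid$cx <- mid$cx + 5
  mid$score <- 1
  a3 <- assign_targets(mid, gts, 0.3)
  l3a <- detection_loss(mid, a3, gts, w_box = 7.5)
  l3b <- detection_loss(mid, a3, gts, w_box = 15)
  expect_equal(
    l3b$total - l3b$cls_term * 0.5 / 0.5,
    2 * (l3a$total - l3a$cls_term * 0.5 / 0.5),
    tolerance = 1e-9
  )
})

test_that("cosine schedule hits its endpoints and decays monotonically", {
  lrs <- vapply(0:109, cosine_lr, numeric(1), epochs = 110, lr0 = 0.01)
  expect_equal(lrs[1], 0.01)
  expect_equal(lrs[110], 1e-4)
  expect_true(all(diff(lrs) < 0))
  expect_equal(cosine_lr(0, 1, 0.01), 0.01)
})

test_that("decoding inverts known raw outputs in both box modes", {
  H <- 4L
  W <- 4L
  s <- 8
  # direct mode: neutral logits put the box at the cell center with the
  # prior size
  box <- matrix(0, H * W, 4)
  box[, 3] <- log(5)
  box[, 4] <- log(1.2)
  ang <- matrix(0, H * W, 1)
  d <- panicleobb:::decode_raw(box, ang, s, H, W, "direct", 16)
  cell5 <- 5 # s0 = 4: i = 0, j = 1
  expect_equal(d$cx[cell5], (1 + 0.5) * s)
  expect_equal(d$cy[cell5], 0.5 * s)
  expect_equal(d$w[cell5], 40)
  expect_equal(d$h[cell5], 9.6)
  expect_equal(d$theta[cell5], 0)

  # dfl mode: saturated logits at bin b decode to distance b (in strides)
  reg_max <- 16L
  box2 <- matrix(-50, H * W, 4 * reg_max)
  put <- function(group, bin) {
    box2[, (group - 1) * reg_max + bin + 1] <<- 50
  }
  put(1, 3) # l = 3
  put(2, 1) # t = 1
  put(3, 3) # r = 3
  put(4, 1) # b = 1
  d2 <- panicleobb:::decode_raw(box2, ang, s, H, W, "dfl", reg_max)
  expect_equal(d2$w, rep(6 * s, H * W), tolerance = 1e-9)
  expect_equal(d2$h, rep(2 * s, H * W), tolerance = 1e-9)
  # symmetric distances keep the center at the cell center
  expect_equal(d2$cx[cell5], (1 + 0.5) * s, tolerance = 1e-9)
})

test_that("training on a tiny dataset decreases the loss and logs epochs", {
  dir <- withr::local_tempdir()
  spec <- scene_spec(
    image_size = 160, n_objects = c(3, 4),
    length_range = c(30, 50), width_range = c(7, 11)
  )
  generate_dataset(spec, n_train = 6, n_val = 2, dir, seed = 1)
  m <- build_oe_yolo(
    model_config(width_mult = 0.125, depth_mult = 0.07, box_mode = "direct"),
    seed = 1
  )
  cfg <- train_config(
    epochs = 3, batch_size = 4, lr0 = 0.01, image_size = 160,
    seed = 1, val_interval = 10
  )
  fit <- train_detector(m, dir, cfg, quiet = TRUE)
  expect_s3_class(fit, "obb_training")
  expect_equal(nrow(fit$log), 3)
  expect_true(all(is.finite(fit$log$loss)))
  expect_lt(fit$log$loss[3], fit$log$loss[1])
  expect_lt(fit$log$lr[3], fit$log$lr[1])

  tl <- tidy(fit)
  expect_identical(tl, fit$log)
  gl <- glance(fit)
  expect_equal(gl$epochs, 3)

  expect_error(
    train_detector(m, withr::local_tempdir(), cfg),
    class = "panicleobb_data_error"
  )

  # detection contract on the trained model
  img <- png::readPNG(list.files(file.path(dir, "images", "val"),
    full.names = TRUE
  )[1])[, , 1:3]
  none <- detect(fit$model, img, conf_thr = 1)
  expect_equal(nrow(none), 0)
  d <- detect(fit$model, img, conf_thr = 0.05, nms_iou = 0.35)
  if (nrow(d) > 1) {
    pairs <- utils::combn(nrow(d), 2)
    expect_true(all(polygon_iou(d[pairs[1, ], ], d[pairs[2, ], ]) <= 0.35 + 1e-9))
  }
  expect_error(detect(fit$model, array(0, c(16, 16, 3))),
    class = "panicleobb_invalid_image"
  )
})

test_that("fixed seeds reproduce the training trajectory", {
  dir <- withr::local_tempdir()
  spec <- scene_spec(
    image_size = 128, n_objects = 3,
    length_range = c(25, 40), width_range = c(6, 10)
  )
  generate_dataset(spec, n_train = 3, n_val = 0, dir, seed = 2)
  run <- function() {
    m <- build_oe_yolo(
      model_config(width_mult = 0.125, depth_mult = 0.07,
        box_mode = "direct"),
      seed = 5
    )
    train_detector(
      m, dir,
      train_config(
        epochs = 2, batch_size = 3, image_size = 128, seed = 5,
        val_interval = 10
      ),
      quiet = TRUE
    )$log$loss
  }
  expect_identical(run(), run())
})
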