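#' Match detections to ground truths at an IoU threshold
#'
#' Greedy matching in descending score order: each detection claims the
#' unmatched ground truth with the highest polygon IoU; it is a true
#' positive when that IoU reaches `iou_thr` (the ground truth then becomes
#' matched and cannot be claimed again), otherwise a false positive.
#' Unmatched ground truths are false negatives.
#'
#' @param dets A detection tibble (box columns + `score`).
#' @param gts Ground-truth oriented boxes.
#' @param iou_thr Matching IoU threshold.
#' @return A list of class `match_result`: per-detection tibble
#'   (`score`, `tp` flag, `matched_gt`), `fn` count and the threshold.
#' @export
match_detections <- function(dets, gts, iou_thr = 0.5) {
  nd <- nrow(dets)
  ng <- nrow(gts)
  ord <- if (nd > 0) order(-dets$score) else integer(0)
  tp <- logical(nd)
  matched_gt <- rep(NA_integer_, nd)
  gt_taken <- logical(ng)
  if (nd > 0 && ng > 0) {
    iou <- matrix(0, nd, ng)
    for (g in seq_len(ng)) iou[, g] <- polygon_iou(dets, gts[g, ])
    for (i in ord) {
      free <- which(!gt_taken)
      if (length(free) == 0) break
      best <- free[which.max(iou[i, free])]
      if (iou[i, best] >= iou_thr) {
        tp[i] <- TRUE
        matched_gt[i] <- best
        gt_taken[best] <- TRUE
      }
    }
  }
  structure(
    list(
      detections = tibble::tibble(
        score = if (nd > 0) dets$score else numeric(0),
        tp = tp, matched_gt = matched_gt
      ),
      fn = sum(!gt_taken), n_gt = ng, iou_thr = iou_thr
    ),
    class = "match_result"
  )
}

#' Precision and recall of a match result
#'
#' `P = TP / (TP + FP)` and `R = TP / (TP + FN)`, with the degenerate-image
#' conventions `P = 1` when there are no detections and `R = 1` when there
#' are no ground truths.
#'
#' @param m A `match_result` from [match_detections()].
#' @return A named list with `precision` and `recall`.
#' @export
precision_recall <- function(m) {
  tp <- sum(m$detections$tp)
  fp <- sum(!m$detections$tp)
  list(
    precision = if (tp + fp == 0) 1 else tp / (tp + fp),
    recall = if (m$n_gt == 0) 1 else tp / m$n_gt
  )
}

#' Average precision with all-point interpolation
#'
#' Detections (pooled over images) are sorted by descending score, the
#' cumulative precision-recall curve is formed, the precision envelope is
#' taken (precision at recall r is the maximum precision at any recall
#' >= r) and AP is the sum of `delta-recall x envelope precision` over the
#' distinct recall steps - the area under the interpolated curve.
#'
#' @param scores Detection scores.
#' @param tp Logical true-positive flags aligned with `scores`.
#' @param n_gt Total number of ground truths.
#' @return AP in \[0, 1\]; `NaN` when `n_gt = 0` and there are no
#'   detections.
#' @export
average_precision <- function(scores, tp, n_gt) {
  if (n_gt == 0) {
    return(if (length(scores) == 0) NaN else 0)
  }
  if (length(scores) == 0 || !any(tp)) {
    return(0)
  }
  ord <- order(-scores)
  tp <- tp[ord]
  cum_tp <- cumsum(tp)
  prec <- cum_tp / seq_along(tp)
  rec <- cum_tp / n_gt
  # envelope: max precision at any recall >= r
  env <- rev(cummax(rev(prec)))
  r_prev <- c(0, rec[-length(rec)])
  sum((rec - r_prev) * env)
}

#' Mean average precision over IoU thresholds
#'
#' Pools per-image detections and ground truths, computes AP per class and
#' per IoU threshold, and averages: `map50` is the value at threshold 0.5,
#' `map50_95` the mean over thresholds 0.50 to 0.95 in steps of 0.05.
#'
#' @param dets_list List of per-image detection tibbles.
#' @param gts_list List of per-image ground-truth tibbles (same length).
#' @param thresholds IoU thresholds (default `seq(0.5, 0.95, 0.05)`).
#' @return A list with `per_threshold` (tibble of threshold, AP), `map`
#'   (vector aligned with `thresholds`), `map50`, `map50_95` (NA when the
#'   corresponding thresholds were not requested), and pooled `precision` /
#'   `recall` at the first threshold.
#' @export
mean_ap <- function(dets_list, gts_list, thresholds = seq(0.5, 0.95, 0.05)) {
  stopifnot(length(dets_list) == length(gts_list), all(thresholds > 0),
    all(thresholds <= 1))
  classes <- sort(unique(c(
    0L,
    unlist(lapply(gts_list, function(g) {
      if ("class_id" %in% names(g)) g$class_id else 0L
    }))
  )))
  ap_mat <- matrix(NA_real_, length(thresholds), length(classes))
  prec <- rec <- NA_real_
  for (ti in seq_along(thresholds)) {
    thr <- thresholds[ti]
    for (ci in seq_along(classes)) {
      scores <- numeric(0)
      tp <- logical(0)
      n_gt <- 0
      tp_tot <- 0
      fp_tot <- 0
      for (i in seq_along(dets_list)) {
        d <- dets_list[[i]]
        g <- gts_list[[i]]
        if ("class_id" %in% names(d)) d <- d[d$class_id == classes[ci], ]
        if ("class_id" %in% names(g)) g <- g[g$class_id == classes[ci], ]
        m <- match_detections(d, g, thr)
        scores <- c(scores, m$detections$score)
        tp <- c(tp, m$detections$tp)
        n_gt <- n_gt + m$n_gt
        tp_tot <- tp_tot + sum(m$detections$tp)
        fp_tot <- fp_tot + sum(!m$detections$tp)
      }
      ap_mat[ti, ci] <- average_precision(scores, tp, n_gt)
      if (ti == 1 && ci == 1) {
        prec <- if (tp_tot + fp_tot == 0) 1 else tp_tot / (tp_tot + fp_tot)
        rec <- if (n_gt == 0) 1 else tp_tot / n_gt
      }
    }
  }
  map <- rowMeans(ap_mat, na.rm = TRUE)
  i50 <- which(abs(thresholds - 0.5) < 1e-9)
  full <- seq(0.5, 0.95, 0.05)
  has_full <- all(vapply(
    full,
    function(t) any(abs(thresholds - t) < 1e-9), logical(1)
  ))
  list(
    per_threshold = tibble::tibble(threshold = thresholds, ap = map),
    map = map,
    map50 = if (length(i50) == 1) map[i50] else NA_real_,
    map50_95 = if (has_full) {
      mean(map[vapply(full, function(t) {
        which(abs(thresholds - t) < 1e-9)[1]
      }, numeric(1))])
    } else {
      NA_real_
    },
    precision = prec, recall = rec
  )
}

#' Panicle-count regression metrics
#'
#' Agreement between per-image predicted and manual counts:
#' `MAE = mean |p - g|`, `RMSE = sqrt(mean (p - g)^2)`,
#' `MAPE = 100 * mean(|p - g| / g)` and `R^2 = 1 - SSres / SStot` about the
#' mean manual count.
#'
#' @param pred_counts,gt_counts Equal-length non-empty integer vectors;
#'   `gt_counts` must be positive for MAPE.
#' @return A tibble of class `count_stats` with `r2`, `mae`, `rmse`, `mape`
#'   and `n`.
#' @export
counting_metrics <- function(pred_counts, gt_counts) {
  if (length(pred_counts) != length(gt_counts)) {
    rlang::abort("count vectors must have equal length",
      class = "panicleobb_data_error"
    )
  }
  if (length(gt_counts) == 0) {
    rlang::abort("count vectors must be non-empty",
      class = "panicleobb_data_error"
    )
  }
  if (any(gt_counts == 0)) {
    rlang::abort("MAPE undefined: a manual count is zero",
      class = "panicleobb_data_error"
    )
  }
  err <- pred_counts - gt_counts
  ss_res <- sum(err^2)
  ss_tot <- sum((gt_counts - mean(gt_counts))^2)
  tibble::new_tibble(
    tibble::tibble(
      r2 = 1 - ss_res / ss_tot,
      mae = mean(abs(err)),
      rmse = sqrt(mean(err^2)),
      mape = 100 * mean(abs(err) / gt_counts),
      n = length(gt_counts)
    ),
    class = "count_stats"
  )
}

#' Count panicles in images by detection
#'
#' Runs [detect()] on each image and counts surviving detections.
#'
#' @param model An `oe_yolo` model.
#' @param images A list of image arrays or a character vector of PNG paths.
#' @param conf_thr,nms_iou Detection thresholds.
#' @return An integer vector of per-image counts.
#' @export
count_panicles <- function(model, images, conf_thr = 0.25, nms_iou = 0.35) {
  vapply(images, function(im) {
    if (is.character(im)) im <- png::readPNG(im)[, , 1:3, drop = FALSE]
    nrow(detect(model, im, conf_thr, nms_iou))
  }, integer(1))
}
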