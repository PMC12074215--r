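# Independent oracles used to cross-check the implementation. Each is a
# deliberately naive algorithm sharing no code path with the functions it
# checks.

# 2-D grid quadrature of the Bhattacharyya coefficient integral
# BC = \int sqrt(p(x) q(x)) dx for two bivariate normal densities given as
# rows of obb_to_gaussian() output.
bc_quadrature <- function(g1, g2, step = NULL) {
  s1 <- sqrt(max(g1$sxx, g1$syy))
  s2 <- sqrt(max(g2$sxx, g2$syy))
  lo_x <- min(g1$mux - 6 * s1, g2$mux - 6 * s2)
  hi_x <- max(g1$mux + 6 * s1, g2$mux + 6 * s2)
  lo_y <- min(g1$muy - 6 * s1, g2$muy - 6 * s2)
  hi_y <- max(g1$muy + 6 * s1, g2$muy + 6 * s2)
  if (is.null(step)) step <- min(s1, s2) / 40
  xs <- seq(lo_x, hi_x, by = step)
  ys <- seq(lo_y, hi_y, by = step)
  dens <- function(g, px, py) {
    det <- g$sxx * g$syy - g$sxy^2
    dx <- px - g$mux
    dy <- py - g$muy
    q <- (g$syy * dx^2 - 2 * g$sxy * dx * dy + g$sxx * dy^2) / det
    exp(-q / 2) / (2 * pi * sqrt(det))
  }
  acc <- 0
  # row-chunked to bound memory on fine grids
  chunk <- max(1L, floor(2e6 / length(xs)))
  i <- 1L
  while (i <= length(ys)) {
    j <- min(i + chunk - 1L, length(ys))
    px <- rep(xs, times = j - i + 1L)
    py <- rep(ys[i:j], each = length(xs))
    acc <- acc + sum(sqrt(dens(g1, px, py) * dens(g2, px, py)))
    i <- j + 1L
  }
  acc * step^2
}

# brute-force greedy NMS over a precomputed pairwise IoU matrix
nms_oracle <- function(dets, thr) {
  n <- nrow(dets)
  cls <- if ("class_id" %in% names(dets)) dets$class_id else rep(0L, n)
  ord <- order(-dets$score, cls, seq_len(n))
  iou <- matrix(0, n, n)
  for (i in seq_len(n)) iou[i, ] <- polygon_iou(dets[rep(i, n), ], dets)
  keep <- integer(0)
  removed <- logical(n)
  for (i in ord) {
    if (removed[i]) next
    keep <- c(keep, i)
    removed[iou[i, ] > thr & seq_len(n) != i] <- TRUE
  }
  dets[keep, ]
}

# exhaustive greedy detection-to-gt matcher following score order
match_oracle <- function(dets, gts, thr) {
  ord <- order(-dets$score)
  taken <- logical(nrow(gts))
  tp <- logical(nrow(dets))
  for (i in ord) {
    best <- -1
    bj <- 0
    for (j in seq_len(nrow(gts))) {
      if (taken[j]) next
      v <- polygon_iou(dets[i, ], gts[j, ])
      if (v > best) {
        best <- v
        bj <- j
      }
    }
    if (bj > 0 && best >= thr) {
      tp[i] <- TRUE
      taken[bj] <- TRUE
    }
  }
  list(tp = tp, fn = sum(!taken))
}

# minimum enclosing rectangle area by dense angle sweep (independent of the
# rotating-calipers route)
min_rect_area_sweep <- function(pts, n_angles = 3600) {
  best <- Inf
  for (a in seq(0, pi / 2, length.out = n_angles)) {
    u <- c(cos(a), sin(a))
    v <- c(-sin(a), cos(a))
    pu <- pts %*% u
    pv <- pts %*% v
    best <- min(best, (max(pu) - min(pu)) * (max(pv) - min(pv)))
  }
  best
}

random_boxes <- function(n, span = 100, wmax = 60, hmax = 30) {
  obb(
    runif(n, -span, span), runif(n, -span, span),
    runif(n, 2, wmax), runif(n, 1, hmax), runif(n, -pi, pi)
  )
}

sorted_vertex_matrix <- function(boxes) {
  v <- quad_mat <- as.matrix(
    obb_vertices(boxes)[, c("x1", "y1", "x2", "y2", "x3", "y3", "x4", "y4")]
  )
  t(apply(v, 1, function(r) {
    pts <- matrix(r, ncol = 2, byrow = TRUE)
    o <- order(round(pts[, 1], 4), round(pts[, 2], 4))
    as.numeric(t(pts[o, ]))
  }))
}
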