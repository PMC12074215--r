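#' Bhattacharyya coefficient between 2-D Gaussians
#'
#' Closed form of `BC = integral sqrt(p(x) q(x)) dx` for two bivariate
#' normals: `BC = exp(-B_D)` with
#' `B_D = 1/8 (mu1-mu2)' S^{-1} (mu1-mu2) + 1/2 log(det S / sqrt(det S1 det S2))`
#' and `S = (S1 + S2)/2`. Vectorized over rows of the two Gaussian tibbles
#' (as produced by [obb_to_gaussian()]).
#'
#' @param g1,g2 Data frames with columns `mux`, `muy`, `sxx`, `sxy`, `syy`;
#'   rows are recycled if one input has a single row.
#' @return A numeric vector of coefficients in (0, 1].
#' @export
bhattacharyya_coefficient <- function(g1, g2) {
  n <- max(nrow(g1), nrow(g2))
  if (nrow(g1) == 1 && n > 1) g1 <- g1[rep(1, n), ]
  if (nrow(g2) == 1 && n > 1) g2 <- g2[rep(1, n), ]
  sxx <- (g1$sxx + g2$sxx) / 2
  sxy <- (g1$sxy + g2$sxy) / 2
  syy <- (g1$syy + g2$syy) / 2
  det_m <- sxx * syy - sxy^2
  det1 <- g1$sxx * g1$syy - g1$sxy^2
  det2 <- g2$sxx * g2$syy - g2$sxy^2
  if (any(det_m <= 0 | det1 <= 0 | det2 <= 0)) {
    rlang::abort("singular or non-PD covariance",
      class = "panicleobb_degenerate"
    )
  }
  dx <- g1$mux - g2$mux
  dy <- g1$muy - g2$muy
  # quadratic form with the inverse of the mixed covariance
  quad <- (syy * dx^2 - 2 * sxy * dx * dy + sxx * dy^2) / det_m
  bd <- quad / 8 + 0.5 * log(det_m / sqrt(det1 * det2))
  exp(-bd)
}

#' Probabilistic IoU of oriented boxes (Hellinger overlap)
#'
#' Overlap surrogate used as the box-regression loss for rotated detection:
#' each box is replaced by its Gaussian surrogate ([obb_to_gaussian()]) and
#' `prob_iou = 1 - HD(p, q)` where `HD = sqrt(1 - BC)` is the Hellinger
#' distance and `BC` the Bhattacharyya coefficient. The measure is symmetric,
#' bounded in \[0, 1\], equal to 1 only for identical boxes, smooth in all
#' five box parameters, and retains gradient signal even for disjoint boxes -
#' the property that makes it preferable to CIoU-style losses for slender,
#' arbitrarily oriented objects.
#'
#' @param a,b Data frames of oriented boxes; rows are paired (single-row
#'   inputs recycle).
#' @param hellinger_sqrt If `FALSE`, uses the literal linear form
#'   `HD = 1 - BC` (so the result equals `BC` itself) instead of the standard
#'   Hellinger metric; provided for comparison only.
#' @return A numeric vector of overlaps in \[0, 1\].
#' @examples
#' a <- obb(0, 0, 2, 2, 0)
#' prob_iou(a, a) # 1
#' prob_iou(a, obb(1, 0, 2, 2, 0))
#' @export
prob_iou <- function(a, b, hellinger_sqrt = TRUE) {
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1 && n > 1) a <- a[rep(1, n), ]
  if (nrow(b) == 1 && n > 1) b <- b[rep(1, n), ]
  validate_obb(a)
  validate_obb(b)
  if (hellinger_sqrt) {
    prob_iou_par(
      a$cx, a$cy, a$w, a$h, a$theta,
      b$cx, b$cy, b$w, b$h, b$theta
    )
  } else {
    bc <- bhattacharyya_coefficient(obb_to_gaussian(a), obb_to_gaussian(b))
    pmin(pmax(bc, 0), 1)
  }
}

# vectorized ProbIoU on bare parameter vectors (hot path: the training
# loss and its finite-difference gradient)
prob_iou_par <- function(px, py, pw, ph, pth, gx, gy, gw, gh, gth) {
  a1 <- pw^2 / 12
  b1 <- ph^2 / 12
  ct <- cos(pth)
  st <- sin(pth)
  sxx1 <- a1 * ct^2 + b1 * st^2
  sxy1 <- (a1 - b1) * ct * st
  syy1 <- a1 * st^2 + b1 * ct^2
  a2 <- gw^2 / 12
  b2 <- gh^2 / 12
  ct2 <- cos(gth)
  st2 <- sin(gth)
  sxx2 <- a2 * ct2^2 + b2 * st2^2
  sxy2 <- (a2 - b2) * ct2 * st2
  syy2 <- a2 * st2^2 + b2 * ct2^2
  sxx <- (sxx1 + sxx2) / 2
  sxy <- (sxy1 + sxy2) / 2
  syy <- (syy1 + syy2) / 2
  det_m <- sxx * syy - sxy^2
  det1 <- sxx1 * syy1 - sxy1^2
  det2 <- sxx2 * syy2 - sxy2^2
  dx <- px - gx
  dy <- py - gy
  quad <- (syy * dx^2 - 2 * sxy * dx * dy + sxx * dy^2) / det_m
  bc <- exp(-(quad / 8 + 0.5 * log(det_m / sqrt(det1 * det2))))
  bc <- pmin(pmax(bc, 0), 1)
  pmin(pmax(1 - sqrt(1 - bc), 0), 1)
}

#' Exact polygon IoU of oriented boxes
#'
#' Intersection-over-union computed exactly: the two rectangles are
#' intersected by Sutherland-Hodgman clipping and the shoelace area of the
#' resulting convex polygon is divided by the union area. This is the IoU
#' used for evaluation matching and non-maximum suppression; the Gaussian
#' surrogate ([prob_iou()]) is reserved for the training loss.
#'
#' @inheritParams prob_iou
#' @return A numeric vector of IoU values in \[0, 1\].
#' @export
polygon_iou <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1 && n > 1) a <- a[rep(1, n), ]
  if (nrow(b) == 1 && n > 1) b <- b[rep(1, n), ]
  validate_obb(a)
  validate_obb(b)
  if (n == 0) {
    return(numeric(0))
  }
  cpp_quad_iou(quad_matrix(obb_vertices(a)), quad_matrix(obb_vertices(b)))
}

#' Rotated non-maximum suppression
#'
#' Greedy score-descending suppression over oriented detections using exact
#' polygon IoU: the highest-scoring detection is kept and all remaining
#' detections overlapping it above `iou_threshold` are discarded; repeat.
#' Ties in score are broken by lower `class_id`, then input order. The
#' default threshold 0.35 keeps valid neighboring panicles in dense canopies
#' while removing duplicates.
#'
#' @param detections A data frame with box columns plus `score` in \[0, 1\]
#'   and integer `class_id`.
#' @param iou_threshold Suppression threshold in \[0, 1\].
#' @return The surviving detections, sorted by descending score.
#' @export
rotated_nms <- function(detections, iou_threshold = 0.35) {
  if (nrow(detections) == 0) {
    return(tibble::as_tibble(detections))
  }
  validate_obb(detections)
  stopifnot(
    all(detections$score >= 0 & detections$score <= 1),
    iou_threshold >= 0, iou_threshold <= 1
  )
  cls <- if ("class_id" %in% names(detections)) detections$class_id else 0L
  ord <- order(-detections$score, cls, seq_len(nrow(detections)))
  d <- tibble::as_tibble(detections)[ord, ]
  quads <- quad_matrix(obb_vertices(d))
  keep <- logical(nrow(d))
  alive <- rep(TRUE, nrow(d))
  for (i in seq_len(nrow(d))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    rest <- which(alive & seq_len(nrow(d)) > i)
    if (length(rest) == 0) next
    iou <- cpp_quad_iou(
      quads[rep(i, length(rest)), , drop = FALSE],
      quads[rest, , drop = FALSE]
    )
    alive[rest[iou > iou_threshold]] <- FALSE
  }
  d[keep, ]
}

#' Brute-force rasterized IoU estimate
#'
#' Estimates the IoU of two oriented boxes by testing a dense regular grid of
#' points over their joint bounding box. Algorithmically independent of the
#' exact clipping computation in [polygon_iou()]; intended as a slow
#' cross-check.
#'
#' @param a,b One-row data frames of oriented boxes.
#' @param n Approximate number of grid points.
#' @return A single IoU estimate.
#' @export
rasterized_iou <- function(a, b, n = 1e7) {
  validate_obb(a)
  validate_obb(b)
  cpp_raster_iou(
    quad_matrix(obb_vertices(a[1, ]))[1, ],
    quad_matrix(obb_vertices(b[1, ]))[1, ],
    n
  )
}
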