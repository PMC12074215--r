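#' Oriented bounding boxes as tibbles
#'
#' An oriented bounding box (OBB) is a rotated rectangle parameterized by its
#' center `(cx, cy)`, side lengths `(w, h)` and rotation angle `theta`, all in
#' image pixel coordinates (origin top-left, x right, y down; `theta` in
#' radians, measured from the +x axis toward +y). `obb()` builds a tibble of
#' boxes, one row per box, in canonical form: `w >= h` and
#' `theta` in `[-pi/2, pi/2)`. Slender objects such as rice panicles make the
#' long-side-first convention natural: `theta` is then the main-stem
#' direction.
#'
#' @param cx,cy Center coordinates in pixels.
#' @param w,h Side lengths in pixels (must be positive). On input `w` and `h`
#'   may be in any order; canonicalization swaps them so that `w >= h`.
#' @param theta Rotation angle in radians (any real; wrapped into
#'   `[-pi/2, pi/2)` using the pi-periodicity of rectangles).
#' @return A tibble with columns `cx`, `cy`, `w`, `h`, `theta` in canonical
#'   form.
#' @examples
#' obb(100, 50, 40, 10, 0)
#' obb(0, 0, 2, 4, 0) # swaps sides, theta becomes -pi/2
#' @export
obb <- function(cx, cy, w, h, theta = 0) {
  df <- tibble::tibble(
    cx = as.double(cx), cy = as.double(cy),
    w = as.double(w), h = as.double(h), theta = as.double(theta)
  )
  canonicalize_obb(df)
}

validate_obb <- function(boxes) {
  need <- c("cx", "cy", "w", "h", "theta")
  miss <- setdiff(need, names(boxes))
  if (length(miss) > 0) {
    rlang::abort(paste0("missing box columns: ", paste(miss, collapse = ", ")),
      class = "panicleobb_invalid_box"
    )
  }
  if (nrow(boxes) > 0 && any(!is.finite(boxes$w) | !is.finite(boxes$h) |
    boxes$w <= 0 | boxes$h <= 0)) {
    rlang::abort("box widths and heights must be positive and finite",
      class = "panicleobb_invalid_box"
    )
  }
  invisible(boxes)
}

#' Canonicalize oriented boxes
#'
#' Rewrites each box so that `w >= h` and `theta` lies in `[-pi/2, pi/2)`
#' while describing the identical rectangle (a rectangle is invariant under
#' `theta -> theta + pi`, and swapping sides rotates by `pi/2`).
#'
#' @param boxes A data frame with columns `cx`, `cy`, `w`, `h`, `theta`.
#' @return A tibble of canonical boxes.
#' @export
canonicalize_obb <- function(boxes) {
  validate_obb(boxes)
  boxes <- tibble::as_tibble(boxes)
  swap <- boxes$w < boxes$h
  if (any(swap)) {
    tmp <- boxes$w[swap]
    boxes$w[swap] <- boxes$h[swap]
    boxes$h[swap] <- tmp
    boxes$theta[swap] <- boxes$theta[swap] + pi / 2
  }
  th <- boxes$theta
  th <- th - pi * floor((th + pi / 2) / pi) # wrap to [-pi/2, pi/2)
  th[th >= pi / 2] <- -pi / 2 # guard the boundary against rounding
  boxes$theta <- th
  boxes
}

#' Box corners as a wide tibble of quadrilateral vertices
#'
#' Returns the four corners `center + R(theta) %*% (+-w/2, +-h/2)` of each
#' box, in a fixed winding order starting from the rotated `(-w/2, -h/2)`
#' corner: for an axis-aligned box the order is top-left, top-right,
#' bottom-right, bottom-left in image coordinates.
#'
#' @param boxes A data frame of oriented boxes.
#' @return A tibble with columns `x1, y1, ..., x4, y4`, one row per box.
#' @export
obb_vertices <- function(boxes) {
  validate_obb(boxes)
  ct <- cos(boxes$theta)
  st <- sin(boxes$theta)
  hw <- boxes$w / 2
  hh <- boxes$h / 2
  # local corner offsets in winding order
  ux <- cbind(-hw, hw, hw, -hw)
  uy <- cbind(-hh, -hh, hh, hh)
  xs <- boxes$cx + ux * ct - uy * st
  ys <- boxes$cy + ux * st + uy * ct
  tibble::tibble(
    x1 = xs[, 1], y1 = ys[, 1], x2 = xs[, 2], y2 = ys[, 2],
    x3 = xs[, 3], y3 = ys[, 3], x4 = xs[, 4], y4 = ys[, 4]
  )
}

quad_matrix <- function(quads) {
  as.matrix(quads[, c("x1", "y1", "x2", "y2", "x3", "y3", "x4", "y4")])
}

#' Fit oriented boxes to quadrilateral vertices
#'
#' The inverse of [obb_vertices()]. Near-rectangular quads are recovered
#' exactly (up to floating point); arbitrary convex quads are replaced by
#' their minimum-area enclosing rotated rectangle (rotating-calipers over the
#' convex hull, as used when re-fitting boxes clipped at tile borders).
#'
#' @param quads A data frame with columns `x1, y1, ..., x4, y4`.
#' @return A tibble of canonical oriented boxes.
#' @export
vertices_to_obb <- function(quads) {
  m <- quad_matrix(quads)
  out <- lapply(seq_len(nrow(m)), function(i) {
    pts <- matrix(m[i, ], ncol = 2, byrow = TRUE)
    min_area_rect(pts)
  })
  canonicalize_obb(dplyr::bind_rows(out))
}

#' Minimum-area enclosing rotated rectangle of a point set
#'
#' Rotating-calipers over the convex hull: the minimum-area enclosing
#' rectangle of a convex polygon has a side collinear with one of the
#' polygon's edges, so it suffices to test each hull edge direction.
#'
#' @param pts A numeric matrix with two columns (x, y), at least 3
#'   non-collinear points.
#' @return A one-row tibble of the enclosing oriented box (canonical form).
#' @export
min_area_rect <- function(pts) {
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  if (nrow(pts) < 3) {
    rlang::abort("need at least 3 points", class = "panicleobb_invalid_quad")
  }
  hull <- grDevices::chull(pts[, 1], pts[, 2])
  hp <- pts[hull, , drop = FALSE]
  n <- nrow(hp)
  if (n < 3) {
    rlang::abort("degenerate (collinear) vertices",
      class = "panicleobb_invalid_quad"
    )
  }
  best <- NULL
  best_area <- Inf
  for (i in seq_len(n)) {
    e <- hp[i %% n + 1, ] - hp[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-12) next
    u <- e / len # edge direction
    v <- c(-u[2], u[1]) # normal
    pu <- hp %*% u
    pv <- hp %*% v
    du <- max(pu) - min(pu)
    dv <- max(pv) - min(pv)
    area <- du * dv
    if (area < best_area - 1e-12) {
      best_area <- area
      cu <- (max(pu) + min(pu)) / 2
      cv <- (max(pv) + min(pv)) / 2
      ctr <- cu * u + cv * v
      best <- c(ctr[1], ctr[2], du, dv, atan2(u[2], u[1]))
    }
  }
  if (is.null(best) || best[3] < 1e-9 || best[4] < 1e-9) {
    rlang::abort("degenerate (collinear) vertices",
      class = "panicleobb_invalid_quad"
    )
  }
  obb(best[1], best[2], best[3], best[4], best[5])
}

#' Gaussian surrogate of oriented boxes
#'
#' Converts each box into the 2-D Gaussian whose mean is the box center and
#' whose covariance carries the second moments of a uniform density over the
#' rectangle: `Sigma = R(theta) diag(w^2/12, h^2/12) R(theta)^T`. This is the
#' probabilistic surrogate underlying the Hellinger-distance box overlap
#' ([prob_iou()]).
#'
#' @param boxes A data frame of oriented boxes.
#' @return A tibble with columns `mux`, `muy`, `sxx`, `sxy`, `syy` (covariance
#'   entries in pixels squared).
#' @export
obb_to_gaussian <- function(boxes) {
  validate_obb(boxes)
  ct <- cos(boxes$theta)
  st <- sin(boxes$theta)
  a <- boxes$w^2 / 12
  b <- boxes$h^2 / 12
  tibble::tibble(
    mux = boxes$cx, muy = boxes$cy,
    sxx = a * ct^2 + b * st^2,
    sxy = (a - b) * ct * st,
    syy = a * st^2 + b * ct^2
  )
}
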