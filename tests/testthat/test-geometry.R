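test_that("canonicalization preserves the rectangle and normalizes the form", {
  b <- obb(0, 0, 2, 4, 0)
  expect_equal(b$w, 4)
  expect_equal(b$h, 2)
  expect_equal(b$theta, -pi / 2)

  b2 <- obb(0, 0, 4, 2, pi)
  expect_equal(b2$theta, 0, tolerance = 1e-12)

  set.seed(42)
  raw <- tibble::tibble(
    cx = runif(50, -50, 50), cy = runif(50, -50, 50),
    w = runif(50, 1, 40), h = runif(50, 1, 40),
    theta = runif(50, -10, 10)
  )
  canon <- canonicalize_obb(raw)
  expect_true(all(canon$w >= canon$h))
  expect_true(all(canon$theta >= -pi / 2 & canon$theta < pi / 2))
  # vertex sets identical up to ordering
  expect_lt(
    max(abs(sorted_vertex_matrix(raw) - sorted_vertex_matrix(canon))), 1e-6
  )
})

test_that("invalid boxes are rejected", {
  expect_error(obb(0, 0, -1, 2, 0), class = "panicleobb_invalid_box")
  expect_error(obb(0, 0, 1, 0, 0), class = "panicleobb_invalid_box")
})

test_that("box vertices follow center + R(theta) * corner offsets", {
  v <- obb_vertices(obb(100, 50, 40, 10, 0))
  expect_equal(as.numeric(v), c(80, 45, 120, 45, 120, 55, 80, 55))

  v2 <- obb_vertices(obb(0, 0, 2, 2, pi / 4))
  d <- sqrt(as.numeric(v2[c("x1", "x2", "x3", "x4")])^2 +
    as.numeric(v2[c("y1", "y2", "y3", "y4")])^2)
  expect_equal(d, rep(sqrt(2), 4), tolerance = 1e-12)

  # side lengths equal w and h
  set.seed(7)
  b <- random_boxes(20)
  v <- obb_vertices(b)
  s1 <- sqrt((v$x2 - v$x1)^2 + (v$y2 - v$y1)^2)
  s2 <- sqrt((v$x3 - v$x2)^2 + (v$y3 - v$y2)^2)
  expect_equal(s1, b$w, tolerance = 1e-6)
  expect_equal(s2, b$h, tolerance = 1e-6)
})

test_that("vertices_to_obb inverts obb_vertices and handles general quads", {
  expect_equal(
    as.numeric(vertices_to_obb(
      tibble::tibble(x1 = 0, y1 = 0, x2 = 2, y2 = 0, x3 = 2, y3 = 2, x4 = 0, y4 = 2)
    )[, c("cx", "cy", "w", "h", "theta")]),
    c(1, 1, 2, 2, 0),
    tolerance = 1e-9
  )

  b <- obb(5, 5, 6, 2, 0.3)
  rt <- vertices_to_obb(obb_vertices(b))
  expect_equal(as.numeric(rt), as.numeric(b), tolerance = 1e-6)

  set.seed(11)
  b <- random_boxes(30)
  rt <- vertices_to_obb(obb_vertices(b))
  expect_lt(max(abs(sorted_vertex_matrix(rt) - sorted_vertex_matrix(b))), 1e-4)

  # arbitrary convex quad: enclosing rectangle at least as large, and
  # minimal against a dense angle-sweep oracle
  set.seed(13)
  for (i in 1:10) {
    base <- matrix(runif(8, 0, 10), 4, 2)
    hull <- grDevices::chull(base)
    quad <- base[hull, , drop = FALSE]
    if (nrow(quad) < 3) next
    rect <- min_area_rect(quad)
    qa <- abs(sum(quad[, 1] * quad[c(2:nrow(quad), 1), 2] -
      quad[c(2:nrow(quad), 1), 1] * quad[, 2])) / 2
    expect_gte(rect$w * rect$h, qa - 1e-9)
    expect_equal(rect$w * rect$h, min_rect_area_sweep(quad), tolerance = 1e-3)
  }

  expect_error(
    min_area_rect(cbind(c(0, 1, 2), c(0, 1, 2))),
    class = "panicleobb_invalid_quad"
  )
})

test_that("gaussian surrogate carries uniform-rectangle second moments", {
  g <- obb_to_gaussian(obb(0, 0, 2, 2, 0))
  expect_equal(c(g$sxx, g$syy, g$sxy), c(1 / 3, 1 / 3, 0))

  g2 <- obb_to_gaussian(obb(0, 0, 4, 2, pi / 2))
  expect_equal(c(g2$sxx, g2$syy), c(1 / 3, 4 / 3), tolerance = 1e-12)

  g3 <- obb_to_gaussian(obb(0, 0, 4, 2, pi / 4))
  R <- matrix(c(cos(pi / 4), sin(pi / 4), -sin(pi / 4), cos(pi / 4)), 2, 2)
  sigma <- R %*% diag(c(16 / 12, 4 / 12)) %*% t(R)
  expect_equal(g3$sxy, 0.5, tolerance = 1e-12)
  expect_equal(
    c(g3$sxx, g3$sxy, g3$syy),
    c(sigma[1, 1], sigma[1, 2], sigma[2, 2]),
    tolerance = 1e-12
  )

  # rotation preserves the determinant: det = (w^2/12)(h^2/12)
  set.seed(5)
  b <- random_boxes(25)
  g <- obb_to_gaussian(b)
  expect_equal(g$sxx * g$syy - g$sxy^2, (b$w^2 / 12) * (b$h^2 / 12),
    tolerance = 1e-9
  )
})

test_that("bhattacharyya coefficient matches its defining integral", {
  g <- obb_to_gaussian(obb(0, 0, 2, 2, 0))
  expect_equal(bhattacharyya_coefficient(g, g), 1)

  far <- obb_to_gaussian(obb(1e6, 0, 2, 2, 0))
  expect_lt(bhattacharyya_coefficient(g, far), 1e-12)

  # unit-variance case against grid quadrature
  g1 <- obb_to_gaussian(obb(0, 0, 2, 2, 0))
  g2 <- obb_to_gaussian(obb(1, 0, 2, 2, 0))
  expect_equal(
    bhattacharyya_coefficient(g1, g2),
    bc_quadrature(g1, g2, step = 0.01),
    tolerance = 1e-3
  )

  set.seed(21)
  b1 <- random_boxes(10, span = 5, wmax = 10, hmax = 6)
  b2 <- random_boxes(10, span = 5, wmax = 10, hmax = 6)
  bc <- bhattacharyya_coefficient(obb_to_gaussian(b1), obb_to_gaussian(b2))
  for (i in 1:10) {
    expect_equal(
      bc[i],
      bc_quadrature(obb_to_gaussian(b1[i, ]), obb_to_gaussian(b2[i, ])),
      tolerance = 1e-3
    )
  }
})

test_that("prob_iou identities, symmetry and rigid-motion invariance", {
  a <- obb(3, -2, 8, 3, 0.7)
  expect_equal(prob_iou(a, a), 1)
  expect_lt(prob_iou(obb(0, 0, 2, 2, 0), obb(1e6, 0, 2, 2, 0)), 1e-9)

  # literal (linear) form equals the Bhattacharyya coefficient itself
  b <- obb(1, 0, 2, 2, 0)
  expect_equal(
    prob_iou(a, b, hellinger_sqrt = FALSE),
    bhattacharyya_coefficient(obb_to_gaussian(a), obb_to_gaussian(b))
  )

  set.seed(31)
  b1 <- random_boxes(50)
  b2 <- random_boxes(50)
  expect_equal(prob_iou(b1, b2), prob_iou(b2, b1), tolerance = 1e-12)
  p0 <- prob_iou(b1, b2)
  expect_true(all(p0 >= 0 & p0 <= 1))
  # common rigid motion: translate by (dx, dy) and rotate both by phi
  phi <- 0.63
  rot <- function(b) {
    ct <- cos(phi)
    st <- sin(phi)
    tibble::tibble(
      cx = b$cx * ct - b$cy * st + 11,
      cy = b$cx * st + b$cy * ct - 7,
      w = b$w, h = b$h, theta = b$theta + phi
    )
  }
  expect_lt(max(abs(prob_iou(rot(b1), rot(b2)) - p0)), 1e-6)
})

test_that("polygon IoU is exact and rigid-motion invariant", {
  a <- obb(0, 0, 2, 2, 0)
  expect_equal(polygon_iou(a, a), 1)
  expect_equal(polygon_iou(a, obb(3, 0, 1, 1, 0)), 0)

  # concentric unit squares rotated 45 degrees: octagonal overlap with
  # closed-form IoU 8(sqrt(2)-1) / (8 - 8(sqrt(2)-1))
  inter <- 8 * (sqrt(2) - 1)
  expect_equal(polygon_iou(a, obb(0, 0, 2, 2, pi / 4)), inter / (8 - inter),
    tolerance = 1e-9
  )

  set.seed(41)
  b1 <- random_boxes(40, span = 20)
  b2 <- random_boxes(40, span = 20)
  v <- polygon_iou(b1, b2)
  expect_equal(v, polygon_iou(b2, b1), tolerance = 1e-12)
  expect_true(all(v >= 0 & v <= 1))
  for (i in seq(1, 40, by = 4)) {
    expect_equal(v[i], rasterized_iou(b1[i, ], b2[i, ], n = 1e6),
      tolerance = 0.01
    )
  }
})

test_that("rotated NMS suppresses greedily by score and matches the oracle", {
  two <- dplyr::bind_rows(obb(0, 0, 4, 2, 0.2), obb(0, 0, 4, 2, 0.2))
  two$score <- c(0.9, 0.8)
  two$class_id <- 0L
  kept <- rotated_nms(two, 0.35)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$score, 0.9)

  disjoint <- dplyr::bind_rows(obb(0, 0, 4, 2, 0), obb(100, 100, 4, 2, 0))
  disjoint$score <- c(0.5, 0.6)
  disjoint$class_id <- 0L
  expect_equal(nrow(rotated_nms(disjoint, 0.35)), 2)

  expect_equal(nrow(rotated_nms(two[0, ], 0.35)), 0)

  set.seed(51)
  d <- random_boxes(50, span = 30, wmax = 30, hmax = 15)
  d$score <- runif(50)
  d$class_id <- 0L
  got <- rotated_nms(d, 0.35)
  want <- nms_oracle(d, 0.35)
  expect_equal(
    got[order(got$cx), c("cx", "cy", "score")],
    want[order(want$cx), c("cx", "cy", "score")]
  )
  # surviving pairs do not overlap above the threshold
  if (nrow(got) > 1) {
    pairs <- utils::combn(nrow(got), 2)
    ious <- polygon_iou(got[pairs[1, ], ], got[pairs[2, ], ])
    expect_true(all(ious <= 0.35 + 1e-12))
  }
})
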