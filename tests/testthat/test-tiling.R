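blank_image <- function(h, w) array(0.5, c(h, w, 3))

test_that("tiling partitions the image into the expected grid", {
  ts <- tile_image(blank_image(608, 608), tile = 608)
  expect_equal(length(ts$tiles), 1)
  expect_equal(unname(ts$grid), c(1, 1))

  ts2 <- tile_image(blank_image(1216, 1216), tile = 608)
  expect_equal(length(ts2$tiles), 4)
  origins <- t(vapply(ts2$tiles, function(t) t$origin, numeric(2)))
  expect_equal(sort(unique(origins[, 1])), c(0, 608))

  # non-divisible size is reflection-padded up to the grid
  ts3 <- tile_image(blank_image(700, 650), tile = 608)
  expect_equal(unname(ts3$grid), c(2, 2))
  expect_true(all(vapply(
    ts3$tiles,
    function(t) all(dim(t$image)[1:2] == c(608, 608)), logical(1)
  )))

  expect_error(tile_image(array(0, c(0, 10, 3))),
    class = "panicleobb_invalid_image"
  )
})

test_that("annotations fully inside a tile are translated; border boxes are
           clipped, re-fit and filtered by retained area", {
  ann <- annotation_record("panicle", obb(800, 700, 60, 12, 0.4))
  ts <- tile_image(blank_image(1216, 1216), ann, tile = 608)
  kept <- lapply(ts$tiles, function(t) t$annotations)
  n_per_tile <- vapply(kept, nrow, integer(1))
  expect_equal(sum(n_per_tile), 1)
  t22 <- ts$tiles[[which(n_per_tile == 1)]]
  expect_equal(unname(t22$origin), c(608, 608))
  expect_equal(
    as.numeric(t22$annotations[, c("cx", "cy", "w", "h", "theta")]),
    c(800 - 608, 700 - 608, 60, 12, 0.4),
    tolerance = 1e-6
  )

  # a box straddling the border: each side keeps a piece iff its retained
  # area fraction reaches the threshold
  straddle <- annotation_record("panicle", obb(608, 300, 100, 20, 0))
  ts2 <- tile_image(blank_image(608, 1216), straddle,
    tile = 608,
    min_area_frac = 0.3
  )
  pieces <- dplyr::bind_rows(lapply(ts2$tiles, function(t) t$annotations))
  expect_equal(nrow(pieces), 2) # split 50/50, both above 0.3
  expect_equal(sort(pieces$w), c(50, 50), tolerance = 1e-6)

  # with a strict filter both halves fall below the threshold and the box
  # is reported as dropped
  ts3 <- tile_image(blank_image(608, 1216), straddle,
    tile = 608,
    min_area_frac = 0.6
  )
  expect_equal(sum(vapply(
    ts3$tiles, function(t) nrow(t$annotations),
    integer(1)
  )), 0)
  expect_equal(nrow(ts3$dropped), 1)
  expect_equal(ts3$dropped$retained_frac, 0.5, tolerance = 1e-6)
})

test_that("every annotation is either kept in a tile or reported dropped", {
  set.seed(91)
  n <- 25
  ann <- annotation_record("panicle", obb(
    runif(n, 20, 1196), runif(n, 20, 1196),
    runif(n, 30, 100), runif(n, 8, 20), runif(n, -pi / 2, pi / 2)
  ))
  ts <- tile_image(blank_image(1216, 1216), ann, tile = 608, min_area_frac = 0.3)
  kept <- dplyr::bind_rows(lapply(ts$tiles, function(t) t$annotations))
  # conservation: kept pieces + dropped >= original count, and each kept
  # piece has retained area >= 0.3 of its source box by construction
  expect_gte(nrow(kept) + nrow(ts$dropped), n)
  expect_true(all(kept$cx >= 0 & kept$cx < 608 & kept$cy >= 0 & kept$cy < 608))
  expect_true(all(kept$w * kept$h <= ann$w[1] * 0 + max(ann$w * ann$h) + 1e-6))
})

test_that("horizontal flip is an involution on pixels and boxes", {
  set.seed(101)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  ann <- annotation_record("panicle", obb(c(20, 40), c(30, 10), c(20, 12),
    c(6, 4), c(0.5, -0.2)))
  spec <- augmentation_spec(
    hflip = 1, scale = NULL, translate = NULL, rotate = NULL,
    contrast = NULL, blur_sigma = NULL
  )
  once <- augment_scene(img, ann, spec, seed = 1)
  twice <- augment_scene(once$image, once$annotations, spec, seed = 2)
  expect_equal(twice$image, img)
  expect_equal(
    as.matrix(twice$annotations[, c("cx", "cy", "w", "h", "theta")]),
    as.matrix(ann[, c("cx", "cy", "w", "h", "theta")]),
    tolerance = 1e-6
  )
})

test_that("photometric-only augmentation leaves annotations untouched", {
  set.seed(111)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  ann <- annotation_record("panicle", obb(30, 30, 20, 8, 0.3))
  spec <- augmentation_spec(
    hflip = NULL, scale = NULL, translate = NULL, rotate = NULL,
    contrast = c(0.8, 1.2), blur_sigma = c(0.5, 1.5)
  )
  out <- augment_scene(img, ann, spec, seed = 5)
  expect_identical(out$annotations, ann)
  expect_false(identical(out$image, img))
})

test_that("pure rotation turns a horizontal box by the same angle", {
  img <- array(0.5, c(128, 128, 3))
  ann <- annotation_record("panicle", obb(64, 64, 40, 10, 0))
  spec <- augmentation_spec(
    hflip = NULL, scale = c(1, 1), translate = NULL, rotate = c(30, 30),
    contrast = NULL, blur_sigma = NULL
  )
  out <- augment_scene(img, ann, spec, seed = 3)
  expect_equal(out$annotations$theta, 30 * pi / 180, tolerance = 1e-6)
  expect_equal(out$annotations$w, 40, tolerance = 1e-6)
})

test_that("identical seeds reproduce augmented output exactly", {
  set.seed(121)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  ann <- annotation_record("panicle", obb(30, 30, 20, 8, 0.3))
  a <- augment_scene(img, ann, seed = 99)
  b <- augment_scene(img, ann, seed = 99)
  expect_identical(a, b)
  c <- augment_scene(img, ann, seed = 100)
  expect_false(identical(a$image, c$image))
})
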