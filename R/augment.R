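#' Augmentation settings
#'
#' Describes which transforms [augment_scene()] applies and their parameter
#' ranges. Geometric transforms (flip, affine) move pixels and boxes
#' identically; photometric transforms (contrast, blur) leave annotations
#' untouched. Set a component to `NULL` to disable it.
#'
#' @param hflip Probability of a horizontal flip.
#' @param scale Length-2 range of isotropic scale factors.
#' @param translate Maximum translation as a fraction of image size.
#' @param rotate Maximum absolute rotation in degrees (or a length-2 range).
#' @param contrast Length-2 range of contrast gains about mid-gray.
#' @param blur_sigma Length-2 range of Gaussian blur standard deviations in
#'   pixels.
#' @return A list of class `augmentation_spec`.
#' @export
augmentation_spec <- function(hflip = 0.5, scale = c(0.8, 1.2),
                              translate = 0.1, rotate = 15,
                              contrast = c(0.8, 1.2),
                              blur_sigma = c(0, 1.5)) {
  structure(
    list(
      hflip = hflip, scale = scale, translate = translate, rotate = rotate,
      contrast = contrast, blur_sigma = blur_sigma
    ),
    class = "augmentation_spec"
  )
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

gaussian_blur <- function(image, sigma) {
  if (sigma < 0.05) {
    return(image)
  }
  r <- ceiling(3 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  H <- dim(image)[1]
  W <- dim(image)[2]
  out <- array(0, dim(image))
  # separable convolution with edge replication, via shifted index vectors
  tmp <- array(0, dim(image))
  for (o in (-r):r) {
    idx <- pmin(pmax(seq_len(H) + o, 1), H)
    tmp <- tmp + k[o + r + 1] * image[idx, , , drop = FALSE]
  }
  for (o in (-r):r) {
    idx <- pmin(pmax(seq_len(W) + o, 1), W)
    out <- out + k[o + r + 1] * tmp[, idx, , drop = FALSE]
  }
  out
}

#' Augment an image and its oriented annotations consistently
#'
#' Applies (in order) an optional horizontal flip, an affine transform
#' (isotropic scale, rotation about the image center, translation), a
#' contrast gain and a Gaussian blur, with all random draws taken from a
#' private stream seeded by `seed` (the same seed reproduces the output
#' exactly). Geometric transforms act on box vertices, which are then re-fit
#' by minimum-area rectangles; a box whose transformed center leaves the
#' frame is dropped and reported in the `dropped` attribute.
#'
#' @param image An `H x W x 3` numeric array in \[0, 1\].
#' @param annotations An annotation tibble.
#' @param spec An [augmentation_spec()].
#' @param seed Integer seed for the private random stream.
#' @return A list with `image`, `annotations` and `dropped`.
#' @export
augment_scene <- function(image, annotations = empty_annotations(),
                          spec = augmentation_spec(), seed = 0L) {
  H <- dim(image)[1]
  W <- dim(image)[2]
  with_seed(seed, {
    ann <- annotations
    # horizontal flip: x -> W - x, theta -> -theta
    if (!is.null(spec$hflip) && runif(1) < spec$hflip) {
      image <- image[, W:1, , drop = FALSE]
      if (nrow(ann) > 0) {
        ann$cx <- W - ann$cx
        ann$theta <- -ann$theta
        ann <- canonicalize_obb(ann)
      }
    }
    # affine: scale + rotation about the center, then translation
    s <- if (is.null(spec$scale)) 1 else runif(1, spec$scale[1], spec$scale[2])
    phi <- if (is.null(spec$rotate)) {
      0
    } else if (length(spec$rotate) == 2) {
      runif(1, spec$rotate[1], spec$rotate[2]) * pi / 180
    } else {
      runif(1, -spec$rotate, spec$rotate) * pi / 180
    }
    tx <- if (is.null(spec$translate)) {
      0
    } else {
      runif(1, -spec$translate, spec$translate) * W
    }
    ty <- if (is.null(spec$translate)) {
      0
    } else {
      runif(1, -spec$translate, spec$translate) * H
    }
    dropped <- empty_annotations()
    if (s != 1 || phi != 0 || tx != 0 || ty != 0) {
      a11 <- s * cos(phi)
      a12 <- -s * sin(phi)
      a21 <- s * sin(phi)
      a22 <- s * cos(phi)
      cxr <- W / 2
      cyr <- H / 2
      # inverse map for nearest-neighbour resampling at pixel centers
      gx <- rep((seq_len(W) - 0.5), each = H)
      gy <- rep((seq_len(H) - 0.5), times = W)
      ux <- gx - cxr - tx
      uy <- gy - cyr - ty
      det <- a11 * a22 - a12 * a21
      sx <- (a22 * ux - a12 * uy) / det + cxr
      sy <- (-a21 * ux + a11 * uy) / det + cyr
      ix <- pmin(pmax(ceiling(sx), 1), W)
      iy <- pmin(pmax(ceiling(sy), 1), H)
      flat <- iy + H * (ix - 1)
      image <- array(
        c(image[, , 1][flat], image[, , 2][flat], image[, , 3][flat]),
        dim = c(H, W, 3)
      )
      if (nrow(ann) > 0) {
        v <- obb_vertices(ann)
        new_rows <- list()
        for (i in seq_len(nrow(ann))) {
          px <- as.numeric(v[i, c("x1", "x2", "x3", "x4")]) - cxr
          py <- as.numeric(v[i, c("y1", "y2", "y3", "y4")]) - cyr
          qx <- a11 * px + a12 * py + cxr + tx
          qy <- a21 * px + a22 * py + cyr + ty
          box <- min_area_rect(cbind(qx, qy))
          rec <- ann[i, ]
          rec$cx <- box$cx
          rec$cy <- box$cy
          rec$w <- box$w
          rec$h <- box$h
          rec$theta <- box$theta
          if (box$cx < 0 || box$cx >= W || box$cy < 0 || box$cy >= H) {
            dropped <- dplyr::bind_rows(dropped, ann[i, ])
          } else {
            new_rows[[length(new_rows) + 1]] <- rec
          }
        }
        ann <- if (length(new_rows) > 0) {
          dplyr::bind_rows(new_rows)
        } else {
          empty_annotations()
        }
      }
    }
    # photometric transforms: annotations untouched
    if (!is.null(spec$contrast)) {
      g <- runif(1, spec$contrast[1], spec$contrast[2])
      image <- clamp01((image - 0.5) * g + 0.5)
    }
    if (!is.null(spec$blur_sigma)) {
      sigma <- runif(1, spec$blur_sigma[1], spec$blur_sigma[2])
      image <- gaussian_blur(image, sigma)
    }
    list(image = image, annotations = ann, dropped = dropped)
  })
}
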