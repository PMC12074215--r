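# Images are numeric arrays H x W x 3 with values in [0, 1]; continuous
# coordinates live in the half-open domain [0, W) x [0, H), pixel (i, j)
# (1-based array indices) covering [j-1, j) x [i-1, i).

reflect_index <- function(n_out, n_in) {
  idx <- seq_len(n_out)
  over <- idx > n_in
  idx[over] <- 2 * n_in - idx[over] + 1 # symmetric reflection at the border
  idx
}

#' Tile an image into fixed-size patches with annotation remapping
#'
#' Splits an image into a `ceiling(H/tile) x ceiling(W/tile)` grid of square
#' patches (reflection-padding the border when the size does not divide; a
#' 5472 x 3648 UAV frame with `tile = 608` divides exactly into 54 tiles).
#' Each annotation's quadrilateral is clipped against every tile; when the
#' retained area is at least `min_area_frac` of the original box area the
#' clipped polygon is re-fit by its minimum-area rotated rectangle and kept
#' in tile-local coordinates, mirroring the annotation protocol that keeps a
#' panicle only when more than 30% of it is visible.
#'
#' @param image An `H x W x 3` numeric array in \[0, 1\].
#' @param annotations An annotation tibble in source-image coordinates.
#' @param tile Tile side length in pixels.
#' @param min_area_frac Minimum retained area fraction for a clipped box.
#' @return An object of class `tile_set`: a list with `tiles` (a list of
#'   `list(image, origin, annotations)`), `tile_size`, `grid` (rows, cols)
#'   and `dropped` (annotations removed by the area filter, with their
#'   retained fraction).
#' @export
tile_image <- function(image, annotations = empty_annotations(), tile = 608,
                       min_area_frac = 0.3) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3 || d[1] == 0 || d[2] == 0) {
    rlang::abort("image must be a non-empty H x W x 3 array",
      class = "panicleobb_invalid_image"
    )
  }
  stopifnot(tile > 0, min_area_frac >= 0, min_area_frac <= 1)
  H <- d[1]
  W <- d[2]
  rows <- ceiling(H / tile)
  cols <- ceiling(W / tile)
  padded <- image[
    reflect_index(rows * tile, H),
    reflect_index(cols * tile, W), ,
    drop = FALSE
  ]
  quads <- if (nrow(annotations) > 0) obb_vertices(annotations) else NULL
  areas <- annotations$w * annotations$h
  kept_any <- rep(FALSE, nrow(annotations))
  best_frac <- rep(0, nrow(annotations))
  tiles <- vector("list", rows * cols)
  t_i <- 0
  for (r in seq_len(rows)) {
    for (cc in seq_len(cols)) {
      x0 <- (cc - 1) * tile
      y0 <- (r - 1) * tile
      clip <- matrix(
        c(x0, y0, x0 + tile, y0, x0 + tile, y0 + tile, x0, y0 + tile),
        ncol = 2, byrow = TRUE
      )
      ann <- empty_annotations()
      if (nrow(annotations) > 0) {
        keep_rows <- list()
        for (i in seq_len(nrow(annotations))) {
          poly <- matrix(as.numeric(quads[i, ]), ncol = 2, byrow = TRUE)
          cp <- cpp_clip_poly(poly, clip)
          if (nrow(cp) < 3) next
          a <- abs(sum(cp[, 1] * cp[c(2:nrow(cp), 1), 2] -
            cp[c(2:nrow(cp), 1), 1] * cp[, 2])) / 2
          frac <- a / areas[i]
          best_frac[i] <- max(best_frac[i], frac)
          if (frac < min_area_frac) next
          kept_any[i] <- TRUE
          box <- min_area_rect(cp)
          rec <- annotations[i, ]
          rec$cx <- box$cx - x0
          rec$cy <- box$cy - y0
          rec$w <- box$w
          rec$h <- box$h
          rec$theta <- box$theta
          rec$tile_dx <- x0
          rec$tile_dy <- y0
          keep_rows[[length(keep_rows) + 1]] <- rec
        }
        if (length(keep_rows) > 0) ann <- dplyr::bind_rows(keep_rows)
      }
      t_i <- t_i + 1
      tiles[[t_i]] <- list(
        image = padded[(y0 + 1):(y0 + tile), (x0 + 1):(x0 + tile), ,
          drop = FALSE
        ],
        origin = c(x = x0, y = y0),
        annotations = ann
      )
    }
  }
  dropped <- annotations[!kept_any & seq_len(nrow(annotations)) > 0, ]
  if (nrow(dropped) > 0) dropped$retained_frac <- best_frac[!kept_any]
  structure(
    list(
      tiles = tiles, tile_size = tile, grid = c(rows = rows, cols = cols),
      dropped = dropped
    ),
    class = "tile_set"
  )
}

#' @export
print.tile_set <- function(x, ...) {
  cat(
    "<tile_set> ", x$grid[["rows"]], "x", x$grid[["cols"]], " tiles of ",
    x$tile_size, " px; ", sum(vapply(x$tiles, function(t) {
      nrow(t$annotations)
    }, integer(1))),
    " annotations kept, ", nrow(x$dropped), " dropped\n",
    sep = ""
  )
  invisible(x)
}
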