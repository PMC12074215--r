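#' Specification of a synthetic panicle scene
#'
#' Describes a randomly generated field scene of slender, oriented,
#' panicle-like objects (textured capsules) over vegetation-like clutter.
#' Presets mimic the two UAV flight heights (3 m and 10 m: the 10 m preset
#' scales object size by 3/10) and the two growth stages (heading: sparser,
#' yellow-green; filling: denser, more golden, heavier overlap). Panicle
#' counts default to the 15-40 per-image range typical of paddy canopies.
#'
#' @param image_size Square image side in pixels.
#' @param n_objects Integer count or length-2 inclusive range.
#' @param length_range,width_range Object long-axis and short-axis ranges in
#'   pixels (before the height-preset scaling).
#' @param curvature_prob Probability that a panicle is drawn bent (two joined
#'   segments).
#' @param overlap_level Maximum allowed pairwise polygon IoU between placed
#'   objects (rejection sampling).
#' @param background Clutter intensity in \[0, 1\].
#' @param height_preset `"3m"` or `"10m"`.
#' @param stage_preset `"heading"` or `"filling"`.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(image_size = 608, n_objects = NULL,
                       length_range = c(60, 120), width_range = c(8, 16),
                       curvature_prob = 0.3, overlap_level = NULL,
                       background = 0.5,
                       height_preset = c("3m", "10m"),
                       stage_preset = c("heading", "filling")) {
  height_preset <- match.arg(height_preset)
  stage_preset <- match.arg(stage_preset)
  if (is.null(n_objects)) {
    n_objects <- if (stage_preset == "heading") c(15, 25) else c(25, 40)
  }
  if (is.null(overlap_level)) {
    overlap_level <- if (stage_preset == "heading") 0.05 else 0.15
  }
  sc <- if (height_preset == "10m") 3 / 10 else 1
  stopifnot(
    image_size > 0, all(n_objects >= 0), all(length_range > 0),
    all(width_range > 0), overlap_level >= 0, overlap_level < 1
  )
  structure(
    list(
      image_size = image_size, n_objects = n_objects,
      length_range = length_range * sc, width_range = width_range * sc,
      curvature_prob = curvature_prob, overlap_level = overlap_level,
      background = background, height_preset = height_preset,
      stage_preset = stage_preset
    ),
    class = "scene_spec"
  )
}

# coarse low-frequency clutter bilinearly upsampled to full resolution
render_background <- function(size, base_rgb, amplitude) {
  coarse_n <- max(8, round(size / 32))
  g <- seq(0, 1, length.out = size)
  cg <- seq(0, 1, length.out = coarse_n)
  interp1 <- function(v) {
    i <- pmin(findInterval(g, cg), coarse_n - 1)
    t <- (g - cg[i]) / (cg[i + 1] - cg[i])
    list(i = i, t = t)
  }
  ix <- interp1(g)
  out <- array(0, c(size, size, 3))
  for (ch in 1:3) {
    coarse <- matrix(rnorm(coarse_n^2, base_rgb[ch], amplitude), coarse_n)
    a <- coarse[ix$i, ix$i] * (1 - ix$t) + coarse[ix$i + 1, ix$i] * ix$t
    b <- coarse[ix$i, ix$i + 1] * (1 - ix$t) + coarse[ix$i + 1, ix$i + 1] * ix$t
    out[, , ch] <- a * (1 - rep(ix$t, each = size)) + b * rep(ix$t, each = size)
  }
  out
}

# distance from points to a segment [p0, p1]
seg_dist <- function(px, py, x0, y0, x1, y1) {
  vx <- x1 - x0
  vy <- y1 - y0
  len2 <- vx^2 + vy^2
  t <- if (len2 > 0) pmin(pmax(((px - x0) * vx + (py - y0) * vy) / len2, 0), 1) else 0
  sqrt((px - (x0 + t * vx))^2 + (py - (y0 + t * vy))^2)
}

#' Generate one synthetic oriented scene
#'
#' Renders `n` textured elongated objects (capsules, optionally bent) over
#' green-brown clutter. The ground-truth oriented box of each object is the
#' minimum-area rotated rectangle of its rendered mask, and rejection
#' sampling enforces a maximum pairwise polygon IoU between objects. The same
#' `spec` and `seed` always reproduce the scene exactly.
#'
#' @param spec A [scene_spec()].
#' @param seed Integer seed.
#' @return A list with `image` (`size x size x 3` array in \[0, 1\]) and
#'   `annotations` (annotation tibble, class `"panicle"`).
#' @export
generate_scene <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(seed, {
    size <- spec$image_size
    heading <- spec$stage_preset == "heading"
    bg_rgb <- if (heading) c(0.20, 0.38, 0.14) else c(0.30, 0.36, 0.16)
    obj_rgb <- if (heading) c(0.72, 0.70, 0.40) else c(0.80, 0.64, 0.30)
    img <- render_background(size, bg_rgb, 0.06)
    # per-pixel speckle scaled by the clutter intensity
    img <- img + spec$background * 0.08 * array(rnorm(size^2 * 3), dim(img))
    img <- clamp01(img)
    n <- if (length(spec$n_objects) == 2) {
      sample(spec$n_objects[1]:spec$n_objects[2], 1)
    } else {
      spec$n_objects
    }
    boxes <- list()
    if (n > 0) {
      for (k in seq_len(n)) {
        placed <- FALSE
        for (attempt in seq_len(1000)) {
          len <- runif(1, spec$length_range[1], spec$length_range[2])
          r <- runif(1, spec$width_range[1], spec$width_range[2]) / 2
          th <- runif(1, -pi / 2, pi / 2)
          margin <- len / 2 + r + 2
          cx <- runif(1, margin, size - margin)
          cy <- runif(1, margin, size - margin)
          bent <- runif(1) < spec$curvature_prob
          if (bent) {
            bend <- sample(c(-1, 1), 1) * runif(1, 15, 35) * pi / 180
            segs <- rbind(
              c(cx, cy, cx + (len / 2 - r) * cos(th - bend / 2),
                cy + (len / 2 - r) * sin(th - bend / 2)),
              c(cx, cy, cx - (len / 2 - r) * cos(th + bend / 2),
                cy - (len / 2 - r) * sin(th + bend / 2))
            )
          } else {
            hx <- (len / 2 - r) * cos(th)
            hy <- (len / 2 - r) * sin(th)
            segs <- rbind(c(cx - hx, cy - hy, cx + hx, cy + hy))
          }
          # pixel-center mask over a local window
          x_lo <- max(1, floor(cx - margin))
          x_hi <- min(size, ceiling(cx + margin))
          y_lo <- max(1, floor(cy - margin))
          y_hi <- min(size, ceiling(cy + margin))
          px <- rep((x_lo:x_hi) - 0.5, each = y_hi - y_lo + 1)
          py <- rep((y_lo:y_hi) - 0.5, times = x_hi - x_lo + 1)
          dist <- seg_dist(px, py, segs[1, 1], segs[1, 2], segs[1, 3], segs[1, 4])
          if (nrow(segs) > 1) {
            dist <- pmin(dist, seg_dist(
              px, py,
              segs[2, 1], segs[2, 2], segs[2, 3], segs[2, 4]
            ))
          }
          inside <- dist <= r
          if (sum(inside) < 8) next
          box <- min_area_rect(cbind(px[inside], py[inside]))
          ok <- TRUE
          if (length(boxes) > 0) {
            prev <- dplyr::bind_rows(boxes)
            if (any(polygon_iou(box, prev) > spec$overlap_level)) ok <- FALSE
          }
          if (!ok) next
          # render: soft-edged capsule with grain-like speckle
          alpha <- pmin(1, pmax(0, (r - dist) / 0.8 + 0.5))
          sel <- which(alpha > 0)
          grain <- 0.85 + 0.30 * runif(length(sel))
          nw <- y_hi - y_lo + 1
          rows_sel <- ((sel - 1) %% nw) + y_lo
          cols_sel <- ((sel - 1) %/% nw) + x_lo
          for (ch in 1:3) {
            flat <- rows_sel + size * (cols_sel - 1) + size * size * (ch - 1)
            img[flat] <- img[flat] * (1 - alpha[sel]) +
              obj_rgb[ch] * grain * alpha[sel]
          }
          box$mask_area <- sum(dist <= r)
          boxes[[length(boxes) + 1]] <- box
          placed <- TRUE
          break
        }
        if (!placed) {
          rlang::abort(
            paste0(
              "could not place object ", k, " of ", n, " under overlap <= ",
              spec$overlap_level, "; lower the density or raise overlap_level"
            ),
            class = "panicleobb_placement_error"
          )
        }
      }
    }
    img <- clamp01(img)
    ann <- if (length(boxes) > 0) {
      all_boxes <- dplyr::bind_rows(boxes)
      rec <- annotation_record("panicle", all_boxes)
      rec$mask_area <- all_boxes$mask_area # rendered-mask pixel count
      rec
    } else {
      empty_annotations()
    }
    list(image = img, annotations = ann)
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_train + n_val` scenes as PNG images with YOLO-OBB label files in
#' the standard detection layout (`images/{train,val}`, `labels/{train,val}`),
#' a YAML manifest naming the classes and splits, and a JSON provenance file
#' recording the spec and seed.
#'
#' @param spec A [scene_spec()].
#' @param n_train,n_val Number of training / validation scenes.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed; per-scene seeds are drawn from it.
#' @return The manifest as a list (invisibly contains file paths).
#' @export
generate_dataset <- function(spec, n_train, n_val, out_dir, seed = 0L) {
  stopifnot(n_train >= 0, n_val >= 0)
  n_tot <- n_train + n_val
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_tot))
  splits <- c(rep("train", n_train), rep("val", n_val))
  for (s in unique(splits)) {
    dir.create(file.path(out_dir, "images", s), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "labels", s), recursive = TRUE, showWarnings = FALSE)
  }
  for (i in seq_len(n_tot)) {
    sc <- generate_scene(spec, seeds[i])
    stem <- sprintf("scene_%04d", i)
    png::writePNG(sc$image, file.path(out_dir, "images", splits[i], paste0(stem, ".png")))
    lines <- dota_to_yolo_obb(
      to_dota(sc$annotations), spec$image_size, spec$image_size
    )
    writeLines(lines, file.path(out_dir, "labels", splits[i], paste0(stem, ".txt")))
  }
  manifest <- list(
    path = normalizePath(out_dir),
    train = "images/train", val = "images/val",
    nc = 1L, names = list("panicle"),
    image_size = spec$image_size
  )
  yaml::write_yaml(manifest, file.path(out_dir, "data.yaml"))
  prov <- list(
    spec = unclass(spec), seed = seed, n_train = n_train, n_val = n_val,
    tool = paste0("panicleobb ", as.character(utils::packageVersion("panicleobb")))
  )
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(manifest)
}

#' List the images and labels of a dataset directory
#'
#' @param dir A dataset directory written by [generate_dataset()] (or laid
#'   out the same way).
#' @param split `"train"` or `"val"`.
#' @return A tibble with `image` and `label` file paths.
#' @export
load_dataset <- function(dir, split = "train") {
  imgs <- sort(list.files(file.path(dir, "images", split),
    pattern = "\\.png$",
    full.names = TRUE
  ))
  labs <- file.path(
    dir, "labels", split,
    sub("\\.png$", ".txt", basename(imgs))
  )
  tibble::tibble(image = imgs, label = labs)
}
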