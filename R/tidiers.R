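#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a training run into its per-epoch log
#'
#' @param x An `obb_training` object from [train_detector()].
#' @param ... Unused.
#' @return The per-epoch log tibble (epoch, learning rate, losses,
#'   validation mAP50 where evaluated).
#' @export
tidy.obb_training <- function(x, ...) {
  x$log
}

#' One-row summary of a training run
#'
#' @param x An `obb_training` object.
#' @param ... Unused.
#' @return A one-row tibble: epochs run, final loss, best and final
#'   validation mAP50, parameter count.
#' @export
glance.obb_training <- function(x, ...) {
  maps <- x$log$val_map50
  tibble::tibble(
    epochs = nrow(x$log),
    final_loss = x$log$loss[nrow(x$log)],
    best_map50 = if (all(is.na(maps))) NA_real_ else max(maps, na.rm = TRUE),
    final_map50 = maps[max(which(!is.na(maps)), 1)],
    params = model_complexity(x$model)$params
  )
}

#' Tidy a match result into its per-detection table
#'
#' @param x A `match_result` from [match_detections()].
#' @param ... Unused.
#' @return A tibble of detections with `score`, `tp`, `matched_gt`.
#' @export
tidy.match_result <- function(x, ...) {
  x$detections
}

#' One-row summary of a match result
#'
#' @param x A `match_result`.
#' @param ... Unused.
#' @return A one-row tibble with TP/FP/FN counts, precision and recall.
#' @export
glance.match_result <- function(x, ...) {
  pr <- precision_recall(x)
  tibble::tibble(
    tp = sum(x$detections$tp), fp = sum(!x$detections$tp), fn = x$fn,
    precision = pr$precision, recall = pr$recall, iou_thr = x$iou_thr
  )
}

obb_polygon_data <- function(boxes) {
  v <- obb_vertices(boxes)
  v$box_id <- seq_len(nrow(v))
  long <- tidyr::pivot_longer(v, -"box_id",
    names_to = c(".value", "vertex"),
    names_pattern = "([xy])([1-4])"
  )
  long
}

#' Plot an image with oriented boxes
#'
#' Renders the image as a raster layer with annotation or detection boxes
#' drawn as rotated rectangles (colored by score when present).
#'
#' @param image An `H x W x 3` array in \[0, 1\] (or `NULL` for boxes only).
#' @param boxes A data frame of oriented boxes (annotations or detections).
#' @return A ggplot object.
#' @export
plot_scene <- function(image = NULL, boxes = NULL) {
  p <- ggplot2::ggplot()
  if (!is.null(image)) {
    H <- dim(image)[1]
    W <- dim(image)[2]
    p <- p + ggplot2::annotation_raster(
      grDevices::as.raster(image), 0, W, -H, 0
    ) +
      ggplot2::xlim(0, W) + ggplot2::ylim(-H, 0)
  }
  if (!is.null(boxes) && nrow(boxes) > 0) {
    d <- obb_polygon_data(boxes)
    d$y <- -d$y
    if ("score" %in% names(boxes)) {
      d$score <- boxes$score[d$box_id]
      p <- p + ggplot2::geom_polygon(
        data = d,
        ggplot2::aes(x = .data$x, y = .data$y, group = .data$box_id,
          color = .data$score),
        fill = NA, linewidth = 0.4
      )
    } else {
      p <- p + ggplot2::geom_polygon(
        data = d,
        ggplot2::aes(x = .data$x, y = .data$y, group = .data$box_id),
        color = "yellow", fill = NA, linewidth = 0.4
      )
    }
  }
  p + ggplot2::coord_fixed() + ggplot2::theme_void()
}

#' Training curves
#'
#' @param object An `obb_training` object.
#' @param ... Unused.
#' @return A ggplot of loss and validation mAP50 against epoch.
#' @export
autoplot.obb_training <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object$log[, c("epoch", "loss", "val_map50")],
    -"epoch",
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(
    d[!is.na(d$value), ],
    ggplot2::aes(x = .data$epoch, y = .data$value)
  ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' Predicted-vs-manual count scatter
#'
#' @param object A `count_stats` tibble from [counting_metrics()] carrying
#'   `pred` and `gt` attributes, or a data frame with `pred` and `gt`
#'   columns.
#' @param ... Unused.
#' @return A ggplot with the identity line and the fitted regression line.
#' @export
plot_counts <- function(object, ...) {
  d <- if (is.data.frame(object) && all(c("pred", "gt") %in% names(object))) {
    object
  } else {
    rlang::abort("need a data frame with pred and gt columns")
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gt, y = .data$pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "manual count", y = "predicted count") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
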