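#' Annotation records
#'
#' Annotations travel as tibbles with one row per labeled object: the class
#' name, a canonical oriented box, a 0/1 difficulty flag, the source image
#' identifier and the (x, y) pixel offset of the tile the record lives in
#' (zero for untiled images).
#'
#' @param class_name Character class labels.
#' @param boxes A data frame of oriented boxes (see [obb()]).
#' @param difficulty Integer 0/1 difficulty flags.
#' @param source Source image identifier.
#' @param tile_dx,tile_dy Tile origin offset in source-image pixels.
#' @return An annotation tibble.
#' @export
annotation_record <- function(class_name, boxes, difficulty = 0L,
                              source = NA_character_, tile_dx = 0, tile_dy = 0) {
  boxes <- canonicalize_obb(boxes)
  tibble::tibble(
    class_name = as.character(class_name),
    cx = boxes$cx, cy = boxes$cy, w = boxes$w, h = boxes$h,
    theta = boxes$theta,
    difficulty = as.integer(difficulty),
    source = as.character(source),
    tile_dx = as.double(tile_dx), tile_dy = as.double(tile_dy)
  )
}

empty_annotations <- function() {
  annotation_record(character(0), obb(double(0), double(0), double(0) + 1,
    double(0) + 1, double(0)))[0, ]
}

xml_num <- function(node, name, what) {
  child <- xml2::xml_find_first(node, name)
  if (is.na(child)) {
    rlang::abort(paste0("missing <", name, "> in ", what),
      class = "panicleobb_parse_error"
    )
  }
  v <- suppressWarnings(as.numeric(xml2::xml_text(child)))
  if (is.na(v)) {
    rlang::abort(paste0("non-numeric <", name, "> in ", what),
      class = "panicleobb_parse_error"
    )
  }
  v
}

#' Parse rolabelImg XML annotations
#'
#' Reads the rolabelImg dialect (`annotation/object/robndbox` elements with
#' `cx`, `cy`, `w`, `h`, `angle`). Angles are the tool's radians in
#' `[0, 2*pi)` and are canonicalized on input; class names are preserved
#' verbatim and object order is kept.
#'
#' @param xml Either a path to an XML file or a length-1 character string of
#'   XML text.
#' @param source Source identifier recorded on each row; defaults to the
#'   `filename` element when present.
#' @return An annotation tibble (see [annotation_record()]).
#' @export
parse_rolabelimg <- function(xml, source = NULL) {
  doc <- tryCatch(
    if (length(xml) == 1 && !grepl("<", xml, fixed = TRUE)) {
      xml2::read_xml(xml)
    } else {
      xml2::read_xml(paste(xml, collapse = "\n"))
    },
    error = function(e) {
      rlang::abort(paste0("malformed XML: ", conditionMessage(e)),
        class = "panicleobb_parse_error"
      )
    }
  )
  if (is.null(source)) {
    fn <- xml2::xml_find_first(doc, ".//filename")
    source <- if (is.na(fn)) NA_character_ else xml2::xml_text(fn)
  }
  objs <- xml2::xml_find_all(doc, ".//object")
  if (length(objs) == 0) {
    return(empty_annotations())
  }
  rows <- lapply(seq_along(objs), function(i) {
    o <- objs[[i]]
    name <- xml2::xml_text(xml2::xml_find_first(o, "name"))
    rb <- xml2::xml_find_first(o, "robndbox")
    what <- paste0("object ", i, " (", name, ")")
    if (is.na(rb)) {
      rlang::abort(paste0("missing <robndbox> in ", what),
        class = "panicleobb_parse_error"
      )
    }
    diff <- xml2::xml_find_first(o, "difficult")
    annotation_record(
      class_name = name,
      boxes = obb(
        xml_num(rb, "cx", what), xml_num(rb, "cy", what),
        xml_num(rb, "w", what), xml_num(rb, "h", what),
        xml_num(rb, "angle", what)
      ),
      difficulty = if (is.na(diff)) 0L else as.integer(xml2::xml_text(diff)),
      source = source
    )
  })
  dplyr::bind_rows(rows)
}

# shortest decimal representation with >= 1 decimal place, <= 1e-4 px error
fmt_coord <- function(x) {
  s <- sprintf("%.4f", x)
  s <- sub("0+$", "", s)
  ifelse(grepl("\\.$", s), paste0(s, "0"), s)
}

#' Convert annotations to DOTA text lines
#'
#' One line per box: the eight vertex coordinates in winding order, the class
#' name and the difficulty flag, space-separated
#' (`"x1 y1 x2 y2 x3 y3 x4 y4 class difficulty"`).
#'
#' @param records An annotation tibble.
#' @return A character vector of DOTA lines (empty for empty input).
#' @export
to_dota <- function(records) {
  if (nrow(records) == 0) {
    return(character(0))
  }
  v <- obb_vertices(records)
  coords <- vapply(seq_len(nrow(v)), function(i) {
    paste(fmt_coord(as.numeric(v[i, c(
      "x1", "y1", "x2", "y2",
      "x3", "y3", "x4", "y4"
    )])), collapse = " ")
  }, character(1))
  paste(coords, records$class_name, records$difficulty)
}

#' Parse DOTA text lines into annotations
#'
#' @param lines Character vector of DOTA lines
#'   (`"x1 y1 ... y4 class difficulty"`).
#' @param source Source identifier recorded on each row.
#' @return An annotation tibble; boxes are re-fit from the vertices.
#' @export
parse_dota <- function(lines, source = NA_character_) {
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(empty_annotations())
  }
  parts <- strsplit(trimws(lines), "\\s+")
  rows <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (length(p) < 9) {
      rlang::abort(paste0("DOTA line ", i, " has fewer than 9 fields"),
        class = "panicleobb_parse_error"
      )
    }
    xy <- suppressWarnings(as.numeric(p[1:8]))
    if (any(is.na(xy))) {
      rlang::abort(paste0("non-numeric coordinates on DOTA line ", i),
        class = "panicleobb_parse_error"
      )
    }
    quad <- tibble::as_tibble(as.list(setNames(
      xy, c("x1", "y1", "x2", "y2", "x3", "y3", "x4", "y4")
    )))
    annotation_record(
      class_name = p[9],
      boxes = vertices_to_obb(quad),
      difficulty = if (length(p) >= 10) as.integer(p[10]) else 0L,
      source = source
    )
  })
  dplyr::bind_rows(rows)
}

#' Convert DOTA lines to YOLO-OBB normalized text
#'
#' Each output line is `"class_index x1 y1 x2 y2 x3 y3 x4 y4"` with vertex
#' coordinates clamped to the image and normalized to \[0, 1\] by the image
#' width and height. Class indices are 0-based positions in `class_map`.
#'
#' @param dota_lines Character vector of DOTA lines.
#' @param image_w,image_h Image dimensions in pixels (positive).
#' @param class_map Named integer vector or character vector of class names;
#'   a bare character vector is mapped to indices `0, 1, ...` in order.
#' @return A character vector of YOLO-OBB lines.
#' @export
dota_to_yolo_obb <- function(dota_lines, image_w, image_h,
                             class_map = c(panicle = 0L)) {
  if (image_w <= 0 || image_h <= 0) {
    rlang::abort("image dimensions must be positive",
      class = "panicleobb_parse_error"
    )
  }
  if (is.character(class_map) && is.null(names(class_map))) {
    class_map <- setNames(seq_along(class_map) - 1L, class_map)
  }
  lines <- dota_lines[nzchar(trimws(dota_lines))]
  if (length(lines) == 0) {
    return(character(0))
  }
  parts <- strsplit(trimws(lines), "\\s+")
  vapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    cls <- p[9]
    if (!cls %in% names(class_map)) {
      rlang::abort(paste0("unknown class name: ", cls),
        class = "panicleobb_class_error"
      )
    }
    xy <- as.numeric(p[1:8])
    xs <- pmin(pmax(xy[c(1, 3, 5, 7)], 0), image_w) / image_w
    ys <- pmin(pmax(xy[c(2, 4, 6, 8)], 0), image_h) / image_h
    paste(
      class_map[[cls]],
      paste(sprintf("%.6f", as.numeric(rbind(xs, ys))), collapse = " ")
    )
  }, character(1))
}

#' Parse YOLO-OBB normalized lines back to annotations
#'
#' @param lines Character vector of `"class_index x1 y1 ... y4"` lines with
#'   normalized coordinates.
#' @param image_w,image_h Image dimensions used to de-normalize.
#' @param class_names Character vector mapping 0-based class indices to
#'   names.
#' @param source Source identifier recorded on each row.
#' @return An annotation tibble.
#' @export
parse_yolo_obb <- function(lines, image_w, image_h,
                           class_names = "panicle", source = NA_character_) {
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(empty_annotations())
  }
  parts <- strsplit(trimws(lines), "\\s+")
  rows <- lapply(seq_along(parts), function(i) {
    p <- as.numeric(parts[[i]])
    if (length(p) != 9 || any(is.na(p))) {
      rlang::abort(paste0("malformed YOLO-OBB line ", i),
        class = "panicleobb_parse_error"
      )
    }
    quad <- tibble::tibble(
      x1 = p[2] * image_w, y1 = p[3] * image_h,
      x2 = p[4] * image_w, y2 = p[5] * image_h,
      x3 = p[6] * image_w, y3 = p[7] * image_h,
      x4 = p[8] * image_w, y4 = p[9] * image_h
    )
    annotation_record(
      class_name = class_names[p[1] + 1],
      boxes = vertices_to_obb(quad),
      source = source
    )
  })
  dplyr::bind_rows(rows)
}
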