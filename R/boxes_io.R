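# Canonical box / annotation data model and annotation file I/O.
#
# Boxes are rows of a tibble.  The canonical internal representation is
# center form in continuous pixel units: columns cx, cy, w, h, with the
# origin at the top-left image corner, x growing right, y growing down.
# Integer coordinates written by labeling tools are read as pixel centers,
# i.e. VOC integer coordinate k corresponds to internal k - 0.5, so a VOC
# box (10, 20, 30, 60) has internal center (19.5, 39.5) and size 20 x 40.

BOX_FRAMES <- c("corner-pixel", "center-pixel", "center-normalized")

#' Construct a box tibble
#'
#' @param cx,cy,w,h numeric vectors: box centers and sizes.
#' @param frame coordinate frame, one of `"center-pixel"` or
#'   `"center-normalized"`.
#' @return a tibble with columns `cx, cy, w, h` and a `box_frame` attribute.
#' @export
box_tibble <- function(cx, cy, w, h, frame = "center-pixel") {
  validate_that(all(w > 0) && all(h > 0), "box width and height must be positive")
  frame <- match.arg(frame, BOX_FRAMES)
  if (frame == "center-normalized") {
    validate_that(all(c(cx - w / 2, cy - h / 2) >= -1e-9) &&
                    all(c(cx + w / 2, cy + h / 2) <= 1 + 1e-9),
                  "normalized boxes must lie in [0, 1]")
  }
  out <- tibble::tibble(cx = cx, cy = cy, w = w, h = h)
  attr(out, "box_frame") <- frame
  out
}

box_frame <- function(boxes) attr(boxes, "box_frame") %||% "center-pixel"

#' Convert boxes between coordinate representations
#'
#' Value-preserving change of representation between `"corner-pixel"`
#' (columns `xmin, ymin, xmax, ymax`), `"center-pixel"` and
#' `"center-normalized"` (columns `cx, cy, w, h`).  Converting to the
#' current representation is the identity.
#'
#' @param boxes a box tibble (from [box_tibble()] or a previous conversion).
#' @param to target representation, one of
#'   `c("corner-pixel", "center-pixel", "center-normalized")`.
#' @param image_size `c(W, H)` in pixels; required whenever the conversion
#'   crosses the pixel/normalized boundary.
#' @return a box tibble in the target representation (extra columns are
#'   carried along).
#' @export
convert_box <- function(boxes, to, image_size = NULL) {
  to <- match.arg(to, BOX_FRAMES)
  from <- box_frame(boxes)
  if (!is.null(image_size)) {
    validate_that(length(image_size) == 2 && all(image_size > 0),
                  "image_size must be two positive numbers (W, H)")
  }
  if (from == to) return(boxes)
  need_size <- xor(from == "center-normalized", to == "center-normalized")
  if (need_size) {
    validate_that(!is.null(image_size),
                  "image_size is required to convert to/from normalized coordinates")
  }
  # to canonical center-pixel
  cp <- switch(from,
    "center-pixel" = boxes,
    "center-normalized" = {
      b <- boxes
      b$cx <- b$cx * image_size[1]; b$w <- b$w * image_size[1]
      b$cy <- b$cy * image_size[2]; b$h <- b$h * image_size[2]
      b
    },
    "corner-pixel" = {
      b <- boxes
      b$cx <- (b$xmin + b$xmax) / 2
      b$cy <- (b$ymin + b$ymax) / 2
      b$w <- b$xmax - b$xmin
      b$h <- b$ymax - b$ymin
      b$xmin <- b$ymin <- b$xmax <- b$ymax <- NULL
      b
    })
  out <- switch(to,
    "center-pixel" = cp,
    "center-normalized" = {
      b <- cp
      b$cx <- b$cx / image_size[1]; b$w <- b$w / image_size[1]
      b$cy <- b$cy / image_size[2]; b$h <- b$h / image_size[2]
      b
    },
    "corner-pixel" = {
      b <- cp
      b$xmin <- b$cx - b$w / 2; b$xmax <- b$cx + b$w / 2
      b$ymin <- b$cy - b$h / 2; b$ymax <- b$cy + b$h / 2
      b$cx <- b$cy <- b$w <- b$h <- NULL
      b
    })
  attr(out, "box_frame") <- to
  out
}

#' Construct a labeled image
#'
#' @param pixels `(H, W, 3)` numeric array with values in `[0, 255]`, or
#'   `NULL` when only annotations are carried.
#' @param annotations annotation tibble: columns `class`, `cx`, `cy`, `w`,
#'   `h` (center-pixel) and `difficult`.
#' @param width,height image size in pixels (derived from `pixels` if given).
#' @param source_id free-text identifier (file stem).
#' @return a `labeled_image` object.
#' @export
labeled_image <- function(pixels = NULL, annotations = empty_annotations(),
                          width = NULL, height = NULL, source_id = "") {
  if (!is.null(pixels)) {
    d <- dim(pixels)
    validate_that(length(d) == 3 && d[3] == 3, "pixels must be (H, W, 3)")
    height <- d[1]; width <- d[2]
  }
  validate_that(!is.null(width) && !is.null(height) && width >= 1 && height >= 1,
                "image dimensions must be >= 1")
  structure(list(pixels = pixels, width = as.numeric(width),
                 height = as.numeric(height),
                 annotations = annotations, source_id = source_id),
            class = "labeled_image")
}

#' @export
print.labeled_image <- function(x, ...) {
  cat(sprintf("<labeled_image> %s: %g x %g px, %d annotation(s)\n",
              if (nzchar(x$source_id)) x$source_id else "(unnamed)",
              x$width, x$height, nrow(x$annotations)))
  invisible(x)
}

empty_annotations <- function() {
  tibble::tibble(class = character(), cx = numeric(), cy = numeric(),
                 w = numeric(), h = numeric(), difficult = logical())
}

# clip center-form boxes to [0, W] x [0, H]; warn if any box moved
clip_annotations <- function(ann, width, height, warn = TRUE) {
  if (nrow(ann) == 0) return(ann)
  xmin <- pmax(ann$cx - ann$w / 2, 0)
  xmax <- pmin(ann$cx + ann$w / 2, width)
  ymin <- pmax(ann$cy - ann$h / 2, 0)
  ymax <- pmin(ann$cy + ann$h / 2, height)
  moved <- xmin > ann$cx - ann$w / 2 + 1e-9 | xmax < ann$cx + ann$w / 2 - 1e-9 |
    ymin > ann$cy - ann$h / 2 + 1e-9 | ymax < ann$cy + ann$h / 2 - 1e-9
  if (any(moved) && warn) {
    rlang::warn(sprintf("%d box(es) extended past image bounds and were clipped",
                        sum(moved)))
  }
  ann$cx <- (xmin + xmax) / 2; ann$w <- xmax - xmin
  ann$cy <- (ymin + ymax) / 2; ann$h <- ymax - ymin
  ann
}

check_classes <- function(cls, classes, allow_unknown) {
  if (allow_unknown) return(invisible(TRUE))
  bad <- setdiff(unique(cls), classes)
  validate_that(length(bad) == 0,
                paste0("unknown class name(s): ", paste(bad, collapse = ", "),
                       " (use allow_unknown = TRUE or extend `classes`)"))
}

## ---- Pascal VOC XML ---------------------------------------------------------

#' Read a Pascal VOC XML annotation file
#'
#' VOC integer corner coordinates are read as pixel centers (VOC
#' coordinate k becomes internal k - 0.5), so a VOC box (10, 20, 30, 60)
#' yields the internal center-form box (19.5, 39.5, 20, 40).  Boxes
#' extending past the image bounds are clipped with a warning.
#'
#' @param path XML file path.
#' @param classes allowed class vocabulary.
#' @param allow_unknown if `TRUE`, class names outside `classes` are kept.
#' @return a [labeled_image()] (pixels not loaded; dimensions attached).
#' @export
read_voc_xml <- function(path, classes = "fish", allow_unknown = FALSE) {
  validate_that(file.exists(path), paste0("annotation file not found: ", path),
                class = "fishdet_io_error")
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    abort_fishdet(paste0("failed to parse XML: ", path, " (", conditionMessage(e), ")"),
                  class = "fishdet_io_error")
  })
  W <- as.numeric(xml2::xml_text(xml2::xml_find_first(doc, ".//size/width")))
  H <- as.numeric(xml2::xml_text(xml2::xml_find_first(doc, ".//size/height")))
  validate_that(is.finite(W) && is.finite(H) && W >= 1 && H >= 1,
                paste0("missing or invalid <size> element in ", path))
  objs <- xml2::xml_find_all(doc, ".//object")
  num <- function(node, q) as.numeric(xml2::xml_text(xml2::xml_find_first(node, q)))
  rows <- lapply(seq_along(objs), function(i) {
    ob <- objs[[i]]
    nm <- xml2::xml_text(xml2::xml_find_first(ob, "./name"))
    xmin <- num(ob, "./bndbox/xmin"); ymin <- num(ob, "./bndbox/ymin")
    xmax <- num(ob, "./bndbox/xmax"); ymax <- num(ob, "./bndbox/ymax")
    validate_that(all(is.finite(c(xmin, ymin, xmax, ymax))),
                  sprintf("object %d ('%s') in %s has a malformed bndbox", i, nm, path))
    validate_that(xmax > xmin && ymax > ymin,
                  sprintf("object %d ('%s') in %s is degenerate: xmin=%g xmax=%g ymin=%g ymax=%g",
                          i, nm, path, xmin, xmax, ymin, ymax))
    dif <- xml2::xml_text(xml2::xml_find_first(ob, "./difficult"))
    tibble::tibble(class = nm,
                   cx = (xmin + xmax) / 2 - 0.5,
                   cy = (ymin + ymax) / 2 - 0.5,
                   w = xmax - xmin, h = ymax - ymin,
                   difficult = !is.na(dif) && identical(dif, "1"))
  })
  ann <- if (length(rows)) dplyr::bind_rows(rows) else empty_annotations()
  check_classes(ann$class, classes, allow_unknown)
  ann <- clip_annotations(ann, W, H)
  fn <- xml2::xml_text(xml2::xml_find_first(doc, ".//filename"))
  sid <- if (!is.na(fn) && nzchar(fn)) tools::file_path_sans_ext(fn) else
    tools::file_path_sans_ext(basename(path))
  labeled_image(annotations = ann, width = W, height = H, source_id = sid)
}

fmt_num <- function(x) {
  ifelse(abs(x - round(x)) < 1e-9, format(round(x), scientific = FALSE),
         format(x, digits = 12, scientific = FALSE))
}

#' Write a Pascal VOC XML annotation file
#'
#' Inverse of [read_voc_xml()]: internal continuous corners map back to the
#' VOC pixel-center dialect (internal corner + 0.5).
#'
#' @param im a [labeled_image()] (pixels may be `NULL`).
#' @param path output XML path.
#' @export
write_voc_xml <- function(im, path) {
  stopifnot(inherits(im, "labeled_image"))
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", "images")
  xml2::xml_add_child(doc, "filename", paste0(im$source_id, ".png"))
  sz <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(sz, "width", fmt_num(im$width))
  xml2::xml_add_child(sz, "height", fmt_num(im$height))
  xml2::xml_add_child(sz, "depth", "3")
  ann <- im$annotations
  for (i in seq_len(nrow(ann))) {
    ob <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(ob, "name", ann$class[i])
    xml2::xml_add_child(ob, "difficult", if (isTRUE(ann$difficult[i])) "1" else "0")
    bb <- xml2::xml_add_child(ob, "bndbox")
    xml2::xml_add_child(bb, "xmin", fmt_num(ann$cx[i] - ann$w[i] / 2 + 0.5))
    xml2::xml_add_child(bb, "ymin", fmt_num(ann$cy[i] - ann$h[i] / 2 + 0.5))
    xml2::xml_add_child(bb, "xmax", fmt_num(ann$cx[i] + ann$w[i] / 2 + 0.5))
    xml2::xml_add_child(bb, "ymax", fmt_num(ann$cy[i] + ann$h[i] / 2 + 0.5))
  }
  ok <- tryCatch({ xml2::write_xml(doc, path); TRUE },
                 error = function(e) FALSE)
  validate_that(ok, paste0("cannot write annotation file: ", path),
                class = "fishdet_io_error")
  invisible(path)
}

## ---- YOLO text dialect ------------------------------------------------------

#' Read a YOLO-style text annotation file
#'
#' One line per object: `class_index cx cy w h`, all box values normalized
#' to `[0, 1]`.
#'
#' @param path text file path.
#' @param image_size `c(W, H)` in pixels.
#' @param classes class vocabulary mapping indices (0-based) to names.
#' @return a [labeled_image()] with center-pixel annotations.
#' @export
read_yolo_txt <- function(path, image_size, classes = "fish") {
  validate_that(file.exists(path), paste0("annotation file not found: ", path),
                class = "fishdet_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  W <- image_size[1]; H <- image_size[2]
  if (length(lines) == 0) {
    ann <- empty_annotations()
  } else {
    m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
    validate_that(ncol(m) == 5 && !anyNA(m),
                  paste0("malformed YOLO annotation line(s) in ", path))
    ci <- as.integer(m[, 1])
    validate_that(all(ci >= 0 & ci < length(classes)),
                  paste0("class index out of vocabulary range in ", path))
    ann <- tibble::tibble(class = classes[ci + 1L],
                          cx = m[, 2] * W, cy = m[, 3] * H,
                          w = m[, 4] * W, h = m[, 5] * H,
                          difficult = FALSE)
  }
  labeled_image(annotations = clip_annotations(ann, W, H), width = W, height = H,
                source_id = tools::file_path_sans_ext(basename(path)))
}

#' Write a YOLO-style text annotation file
#'
#' @inheritParams write_voc_xml
#' @param classes class vocabulary (0-based indices are positions here).
#' @export
write_yolo_txt <- function(im, path, classes = "fish") {
  stopifnot(inherits(im, "labeled_image"))
  ann <- im$annotations
  ci <- match(ann$class, classes) - 1L
  validate_that(!anyNA(ci), "annotation class outside the given vocabulary")
  lines <- sprintf("%d %s %s %s %s", ci,
                   fmt_num(ann$cx / im$width), fmt_num(ann$cy / im$height),
                   fmt_num(ann$w / im$width), fmt_num(ann$h / im$height))
  ok <- tryCatch({ writeLines(lines, path); TRUE }, error = function(e) FALSE)
  validate_that(ok, paste0("cannot write annotation file: ", path),
                class = "fishdet_io_error")
  invisible(path)
}

#' Read an annotation file, dispatching on extension
#'
#' `.xml` files are parsed as Pascal VOC, `.txt` as YOLO text lines.
#'
#' @inheritParams read_yolo_txt
#' @param image_size required for the YOLO dialect only.
#' @export
read_annotations <- function(path, image_size = NULL, classes = "fish",
                             allow_unknown = FALSE) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    xml = read_voc_xml(path, classes, allow_unknown),
    txt = {
      validate_that(!is.null(image_size), "image_size is required for YOLO .txt files")
      read_yolo_txt(path, image_size, classes)
    },
    abort_fishdet(paste0("unsupported annotation extension: .", ext),
                  "fishdet_io_error"))
}

## ---- images and dataset layout ----------------------------------------------

#' Read an image file into a (H, W, 3) 0-255 array
#' @param path a PNG file path.
#' @export
read_image <- function(path) {
  validate_that(file.exists(path), paste0("image not found: ", path),
                class = "fishdet_io_error")
  px <- png::readPNG(path)
  if (length(dim(px)) == 2) px <- array(rep(px, 3), dim = c(dim(px), 3))
  if (dim(px)[3] == 4) px <- px[, , 1:3, drop = FALSE]
  px * 255
}

#' Write a (H, W, 3) 0-255 array as PNG
#' @param pixels the image array.
#' @param path output path.
#' @export
write_image <- function(pixels, path) {
  png::writePNG(pmin(pmax(pixels / 255, 0), 1), path)
  invisible(path)
}

#' Index a dataset directory
#'
#' Expects the `images/` + `labels/` layout with matching file stems;
#' labels may be VOC `.xml` or YOLO `.txt`.
#'
#' @param dir dataset root (or one split of it).
#' @return tibble with columns `stem`, `image`, `label`.
#' @export
index_dataset <- function(dir) {
  validate_that(dir.exists(file.path(dir, "images")),
                paste0("no images/ directory under ", dir), class = "fishdet_io_error")
  imgs <- list.files(file.path(dir, "images"), pattern = "\\.png$", full.names = TRUE)
  stems <- tools::file_path_sans_ext(basename(imgs))
  lab <- vapply(stems, function(s) {
    for (ext in c(".xml", ".txt")) {
      p <- file.path(dir, "labels", paste0(s, ext))
      if (file.exists(p)) return(p)
    }
    NA_character_
  }, character(1))
  tibble::tibble(stem = stems, image = imgs, label = unname(lab))
}

#' Load one dataset entry as a labeled image
#'
#' @param image,label file paths (label may be `NA` for an unlabeled image).
#' @param classes class vocabulary.
#' @export
load_labeled_image <- function(image, label = NA, classes = "fish") {
  px <- read_image(image)
  d <- dim(px)
  ann <- if (is.na(label)) empty_annotations() else
    read_annotations(label, image_size = c(d[2], d[1]), classes = classes)$annotations
  labeled_image(pixels = px, annotations = ann,
                source_id = tools::file_path_sans_ext(basename(image)))
}
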