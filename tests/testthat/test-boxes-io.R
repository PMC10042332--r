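test_that("VOC XML corners convert to the internal center convention", {
  xml <- tempfile(fileext = ".xml")
  writeLines(c(
    "<annotation><filename>a.png</filename>",
    "<size><width>100</width><height>100</height><depth>3</depth></size>",
    "<object><name>fish</name><difficult>0</difficult>",
    "<bndbox><xmin>10</xmin><ymin>20</ymin><xmax>30</xmax><ymax>60</ymax></bndbox>",
    "</object></annotation>"), xml)
  li <- read_voc_xml(xml)
  expect_equal(nrow(li$annotations), 1)
  expect_equal(li$width, 100)
  expect_equal(unlist(li$annotations[1, c("cx", "cy", "w", "h")]),
               c(cx = 19.5, cy = 39.5, w = 20, h = 40))
})

test_that("degenerate and malformed VOC inputs error informatively", {
  xml <- tempfile(fileext = ".xml")
  writeLines(c(
    "<annotation><size><width>50</width><height>50</height></size>",
    "<object><name>fish</name>",
    "<bndbox><xmin>10</xmin><ymin>20</ymin><xmax>10</xmax><ymax>30</ymax></bndbox>",
    "</object></annotation>"), xml)
  expect_error(read_voc_xml(xml), "degenerate")
  expect_error(read_voc_xml(tempfile(fileext = ".xml")), "not found",
               class = "fishdet_io_error")
  bad <- tempfile(fileext = ".xml")
  writeLines("<annotation><object>", bad)
  expect_error(read_voc_xml(bad), class = "fishdet_io_error")
})

test_that("VOC write/read round-trips arbitrary annotation sets exactly", {
  for (seed in 1:5) {
    n <- seed * 3
    ann <- random_annotations(n, seed = seed)
    im <- labeled_image(annotations = ann, width = 200, height = 200,
                        source_id = "rt")
    path <- tempfile(fileext = ".xml")
    write_voc_xml(im, path)
    back <- read_voc_xml(path)
    expect_equal(back$annotations, ann, tolerance = 1e-9)
    expect_equal(back$width, 200)
  }
  # empty set -> valid XML with zero objects
  im0 <- labeled_image(annotations = fishdet:::empty_annotations(),
                       width = 10, height = 10, source_id = "empty")
  p0 <- tempfile(fileext = ".xml")
  write_voc_xml(im0, p0)
  expect_equal(nrow(read_voc_xml(p0)$annotations), 0)
  expect_length(xml2::xml_find_all(xml2::read_xml(p0), ".//object"), 0)
  # order preserved
  ann3 <- random_annotations(3, seed = 9)
  p3 <- tempfile(fileext = ".xml")
  write_voc_xml(labeled_image(annotations = ann3, width = 200, height = 200), p3)
  expect_equal(read_voc_xml(p3)$annotations$cx, ann3$cx, tolerance = 1e-9)
})

test_that("YOLO text dialect round-trips and dispatches by extension", {
  ann <- random_annotations(4, seed = 3)
  im <- labeled_image(annotations = ann, width = 200, height = 200)
  path <- tempfile(fileext = ".txt")
  write_yolo_txt(im, path)
  back <- read_annotations(path, image_size = c(200, 200))
  expect_equal(back$annotations[, c("cx", "cy", "w", "h")],
               ann[, c("cx", "cy", "w", "h")], tolerance = 1e-6)
  expect_error(read_annotations(tempfile(fileext = ".json")), "unsupported")
  expect_error(read_yolo_txt(path, c(200, 200), classes = character(0)),
               "out of vocabulary")
})

test_that("boxes extending past bounds are clipped with a warning", {
  xml <- tempfile(fileext = ".xml")
  writeLines(c(
    "<annotation><size><width>50</width><height>50</height></size>",
    "<object><name>fish</name>",
    "<bndbox><xmin>40</xmin><ymin>10</ymin><xmax>70</xmax><ymax>30</ymax></bndbox>",
    "</object></annotation>"), xml)
  expect_warning(li <- read_voc_xml(xml), "clipped")
  corners <- convert_box(li$annotations, "corner-pixel")
  expect_true(all(corners$xmax <= 50 & corners$xmin >= 0))
})

test_that("unknown class names are rejected unless allowed", {
  xml <- tempfile(fileext = ".xml")
  writeLines(c(
    "<annotation><size><width>50</width><height>50</height></size>",
    "<object><name>eel</name>",
    "<bndbox><xmin>10</xmin><ymin>10</ymin><xmax>20</xmax><ymax>20</ymax></bndbox>",
    "</object></annotation>"), xml)
  expect_error(read_voc_xml(xml), "unknown class")
  expect_equal(read_voc_xml(xml, allow_unknown = TRUE)$annotations$class, "eel")
})

test_that("convert_box worked examples hold", {
  b <- box_tibble(50, 50, 20, 10)
  n <- convert_box(b, "center-normalized", image_size = c(100, 100))
  expect_equal(unlist(n[1, c("cx", "cy", "w", "h")]),
               c(cx = 0.5, cy = 0.5, w = 0.2, h = 0.1))
  corner <- tibble::tibble(xmin = 0, ymin = 0, xmax = 100, ymax = 100)
  attr(corner, "box_frame") <- "corner-pixel"
  cn <- convert_box(corner, "center-normalized", image_size = c(100, 100))
  expect_equal(unlist(cn[1, c("cx", "cy", "w", "h")]),
               c(cx = 0.5, cy = 0.5, w = 1, h = 1))
  expect_error(convert_box(b, "center-normalized", image_size = c(-1, 100)),
               "positive")
  expect_identical(convert_box(b, "center-pixel"), b)
})

test_that("conversion chains over all representation pairs return the start", {
  reps <- c("corner-pixel", "center-pixel", "center-normalized")
  start <- box_tibble(cx = c(30.5, 61.2), cy = c(40.1, 12.3),
                      w = c(10.4, 3.3), h = c(8.8, 17.9))
  for (r1 in reps) for (r2 in reps) {
    out <- convert_box(start, r1, c(100, 100))
    out <- convert_box(out, r2, c(100, 100))
    out <- convert_box(out, "center-pixel", c(100, 100))
    expect_equal(out$cx, start$cx, tolerance = 1e-9)
    expect_equal(out$w, start$w, tolerance = 1e-9)
    expect_equal(out$h, start$h, tolerance = 1e-9)
  }
})

test_that("parsed boxes satisfy 0 <= xmin < xmax <= W in corner form", {
  scenes <- tiny_scenes(21, 1:3)
  for (im in scenes) {
    cc <- convert_box(im$annotations, "corner-pixel")
    expect_true(all(cc$xmin >= 0 & cc$xmin < cc$xmax & cc$xmax <= im$width))
    expect_true(all(cc$ymin >= 0 & cc$ymin < cc$ymax & cc$ymax <= im$height))
  }
})
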