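# IoU/CIoU box math, BCE components, target assignment, composite loss.

corner_box <- function(x1, y1, x2, y2) {
  tibble::tibble(cx = (x1 + x2) / 2, cy = (y1 + y2) / 2, w = x2 - x1, h = y2 - y1)
}

test_that("iou matches direct area arithmetic", {
  a <- corner_box(0, 0, 2, 2)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, corner_box(5, 5, 7, 7)), 0)
  expect_equal(iou(a, corner_box(1, 1, 3, 3)), 1 / 7)
  expect_error(iou(a, tibble::tibble(cx = 1, cy = 1, w = 0, h = 2)), "degenerate")
})

test_that("ciou worked cases hold analytically", {
  a <- corner_box(0, 0, 2, 4)
  expect_equal(ciou(a, a), 1)
  # concentric, equal aspect ratio: penalty terms vanish, CIoU = IoU exactly
  big <- corner_box(-2, -4, 2, 4)
  small <- corner_box(-1, -2, 1, 2)
  expect_identical(ciou(small, big), iou(small, big))
  # derived pair against the independent scalar evaluation
  g <- corner_box(1, 0, 3, 2)
  expect_equal(ciou(a, g), ciou_reference(a, g), tolerance = 1e-12)
})

test_that("ciou never exceeds iou and is 1 only for identical boxes", {
  p <- random_boxes(2000, seed = 2)
  g <- random_boxes(2000, seed = 3)
  ci <- ciou(p, g)
  io <- iou(p, g)
  expect_true(all(ci <= io + 1e-12))
  expect_true(all(ci <= 1))
  expect_true(all(1 - ci >= 0 & 1 - ci < 2.5))  # sup = 1 + 1 + v^2/(1+v)
  same <- abs(ci - 1) < 1e-12
  ident <- abs(p$cx - g$cx) < 1e-12 & abs(p$cy - g$cy) < 1e-12 &
    abs(p$w - g$w) < 1e-12 & abs(p$h - g$h) < 1e-12
  expect_equal(same, ident)
})

test_that("bbox_loss averages 1 - CIoU over matches", {
  a <- corner_box(0, 0, 2, 4)
  g <- corner_box(1, 0, 3, 2)
  expect_equal(bbox_loss(a, a), 0)
  expect_equal(bbox_loss(a, g), 1 - ciou(a, g))
  expect_message(z <- bbox_loss(a[0, ], g[0, ]), "empty")
  expect_equal(z, 0)
})

test_that("confidence loss reproduces hand-evaluated BCE", {
  # all positions no-object, predicted probability 0 -> 0
  expect_equal(confidence_loss(array(0, c(4, 4, 3)), array(FALSE, c(4, 4, 3))), 0)
  # one object position, predicted 0.5, no no-object term -> -ln(0.5)
  expect_equal(confidence_loss(0.5, TRUE), -log(0.5), tolerance = 1e-9)
  # doubling lambda_noobj doubles the no-object contribution exactly
  pred <- array(runif(48), c(4, 4, 3))
  mask <- array(FALSE, c(4, 4, 3)); mask[1, 1, 1] <- TRUE
  l1 <- confidence_loss(pred, mask, lambda_noobj = 0.5)
  l2 <- confidence_loss(pred, mask, lambda_noobj = 1.0)
  obj_part <- confidence_loss(pred, mask, lambda_noobj = 0)
  expect_equal(l2 - obj_part, 2 * (l1 - obj_part), tolerance = 1e-12)
  expect_error(confidence_loss(c(0.1, 0.2), TRUE), "same shape")
})

test_that("class loss gates on object positions and hand BCE", {
  expect_equal(class_loss(matrix(1, 3, 1), rep(0L, 3)), 0, tolerance = 1e-6)
  expect_equal(class_loss(matrix(0.5, 1, 1), 0L), -log(0.5), tolerance = 1e-9)
  expect_equal(class_loss(matrix(numeric(0), 0, 1), integer(0)), 0)
  expect_error(class_loss(matrix(0.5, 1, 2), 2L), "out of range")
})

test_that("target assignment follows the ratio and neighbour-cell rule", {
  anc <- default_anchors(160L)
  # gt exactly equal to an anchor, at a cell center
  g <- tibble::tibble(class = "fish", cx = 8 * 3 + 4, cy = 8 * 5 + 4,
                      w = anc$w[1], h = anc$h[1], difficult = FALSE)
  tg <- assign_targets(g, anc, 160L)
  expect_true(any(tg$scale == 1 & tg$anchor == 1 & tg$gi == 3 & tg$gj == 5))
  # gt 10x larger than every anchor: zero positives, warning
  g2 <- tibble::tibble(class = "fish", cx = 80, cy = 80,
                       w = 10 * max(anc$w), h = 10 * max(anc$h), difficult = FALSE)
  expect_warning(tg2 <- assign_targets(g2, anc, 160L), "matched no anchor|no ground-truth")
  expect_equal(nrow(tg2), 0)
  expect_error(assign_targets(tibble::tibble(class = "fish", cx = 300, cy = 10,
                                             w = 5, h = 5, difficult = FALSE),
                              anc, 160L), "outside")
})

test_that("assignment equals an exhaustive scan over anchor/cell pairs", {
  anc <- default_anchors(160L)
  ann <- random_annotations(6, W = 150, H = 150, seed = 4)
  got <- suppressWarnings(assign_targets(ann, anc, 160L))
  am <- fishdet:::anchor_matrix(anc)
  rows <- list()
  for (s in 1:3) {
    st <- c(8, 16, 32)[s]
    K <- 160 %/% st
    asc <- am[am[, "scale"] == s, , drop = FALSE]
    for (g in seq_len(nrow(ann))) for (a in 1:3) {
      r <- max(ann$w[g] / asc[a, 1], asc[a, 1] / ann$w[g],
               ann$h[g] / asc[a, 2], asc[a, 2] / ann$h[g])
      if (r >= 4) next
      fx <- ann$cx[g] / st; fy <- ann$cy[g] / st
      for (i in 0:(K - 1)) for (j in 0:(K - 1)) {
        center <- i == floor(fx) && j == floor(fy)
        nbx <- j == floor(fy) &&
          i == (if (fx - floor(fx) < 0.5) floor(fx) - 1 else floor(fx) + 1)
        nby <- i == floor(fx) &&
          j == (if (fy - floor(fy) < 0.5) floor(fy) - 1 else floor(fy) + 1)
        if (center || nbx || nby) {
          rows[[length(rows) + 1L]] <- c(s, a, i, j, g)
        }
      }
    }
  }
  want <- unique(do.call(rbind, rows))
  gotm <- unique(as.matrix(got[, c("scale", "anchor", "gi", "gj", "gt")]))
  expect_equal(nrow(gotm), nrow(want))
  key <- function(m) sort(apply(m, 1, paste, collapse = "_"))
  expect_identical(key(gotm), key(want))
})

test_that("the composite loss is invariant to ground-truth ordering", {
  scenes <- tiny_scenes(33, 1)
  im <- scenes[[1]]
  m <- build_model(tiny_model_config(), seed = 2)
  l1 <- detection_loss(m, im)
  im2 <- im
  im2$annotations <- im$annotations[rev(seq_len(nrow(im$annotations))), ]
  l2 <- detection_loss(m, im2)
  expect_equal(l1$total, l2$total, tolerance = 1e-12)
  # components are nonnegative and sum to the total
  expect_true(all(unlist(l1) >= 0))
  expect_equal(l1$total, l1$l_bbox + l1$l_cfd + l1$l_cls, tolerance = 1e-12)
})

test_that("loss decreases over the first training iterations on one image", {
  scenes <- tiny_scenes(34, 1)
  m <- build_model(tiny_model_config(), seed = 3)
  run <- train_detector(m, scenes, NULL, epochs = 10, batch_size = 1,
                        lr = 0.005, seed = 1)
  expect_lt(run$log$train_loss[10], run$log$train_loss[1])
})
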