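# Mosaic-8, photometric jitter, and K-means prior boxes.

make_dot_image <- function(W = 80, H = 80, cx = 40, cy = 40, w = 10, h = 8) {
  px <- array(20, c(H, W, 3))
  labeled_image(pixels = px,
                annotations = tibble::tibble(class = "fish", cx = cx, cy = cy,
                                             w = w, h = h, difficult = FALSE))
}

# independent re-projection of input boxes through the recorded affine
# placements, applying the clip/drop rule
reproject_boxes <- function(images, transforms, cfg) {
  out <- list()
  for (k in seq_along(images)) {
    tr <- transforms[[k]]
    ann <- images[[k]]$annotations
    if (nrow(ann) == 0) next
    cx <- ann$cx * tr$sx - tr$ox + tr$cell[1]
    cy <- ann$cy * tr$sy - tr$oy + tr$cell[2]
    w <- ann$w * tr$sx; h <- ann$h * tr$sy
    xmin <- pmax(cx - w / 2, tr$cell[1]); xmax <- pmin(cx + w / 2, tr$cell[3])
    ymin <- pmax(cy - h / 2, tr$cell[2]); ymax <- pmin(cy + h / 2, tr$cell[4])
    wn <- pmax(xmax - xmin, 0); hn <- pmax(ymax - ymin, 0)
    keep <- wn * hn >= cfg$min_box_area_px & wn * hn >= cfg$min_box_frac * w * h
    if (any(keep)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        cx = ((xmin + xmax) / 2)[keep], cy = ((ymin + ymax) / 2)[keep],
        w = wn[keep], h = hn[keep])
    }
  }
  dplyr::bind_rows(out)
}

test_that("mosaic8 with zero jitter keeps one centrally placed box per cell", {
  ims <- lapply(1:8, function(i) make_dot_image())
  cfg <- augment_config(boundary_jitter = 0, scale_jitter = 0,
                        noise_sigma_range = c(0, 0), brightness_range = c(1, 1),
                        canvas_size = 320L, seed = 4)
  mo <- mosaic8(ims, cfg)
  expect_equal(nrow(mo$annotations), 8)
  # one box inside each cell
  tr <- attr(mo, "transforms")
  for (k in 1:8) {
    cell <- tr[[k]]$cell
    inside <- mo$annotations$cx > cell[1] & mo$annotations$cx < cell[3] &
      mo$annotations$cy > cell[2] & mo$annotations$cy < cell[4]
    expect_equal(sum(inside), 1)
  }
})

test_that("mosaic8 is deterministic and validates its input count", {
  ims <- lapply(1:8, function(i) make_dot_image(cx = 20 + i, cy = 30, w = 8, h = 6))
  cfg <- augment_config(seed = 11, canvas_size = 320L)
  a <- mosaic8(ims, cfg)
  b <- mosaic8(ims, cfg)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$annotations, b$annotations)
  expect_error(mosaic8(ims[1:7], cfg), "exactly 8")
})

test_that("mosaic8 conserves labels under the recorded affine placements", {
  withr::with_seed(3, {
    ims <- lapply(1:8, function(i) {
      ann <- random_annotations(sample(0:3, 1), W = 80, H = 80, seed = i * 7)
      labeled_image(pixels = array(runif(80 * 80 * 3, 0, 255), c(80, 80, 3)),
                    annotations = ann)
    })
  })
  for (sd in c(2, 5, 9)) {
    cfg <- augment_config(seed = sd, canvas_size = 320L,
                          noise_sigma_range = c(0, 0), brightness_range = c(1, 1))
    mo <- mosaic8(ims, cfg)
    expected <- reproject_boxes(ims, attr(mo, "transforms"), cfg)
    got <- mo$annotations[, c("cx", "cy", "w", "h")]
    expect_equal(dplyr::arrange(got, cx, cy),
                 dplyr::arrange(expected, cx, cy), tolerance = 1e-9)
  }
})

test_that("a box wholly inside the cropped-away region is dropped", {
  # corner box with heavy scale jitter: find a seed whose crop removes it,
  # then check agreement with the independent re-projection
  ims <- lapply(1:8, function(i) make_dot_image(cx = 6, cy = 6, w = 8, h = 8))
  dropped <- FALSE
  for (sd in 1:30) {
    cfg <- augment_config(seed = sd, scale_jitter = 1.5, canvas_size = 320L,
                          noise_sigma_range = c(0, 0), brightness_range = c(1, 1))
    mo <- mosaic8(ims, cfg)
    expected <- reproject_boxes(ims, attr(mo, "transforms"), cfg)
    expect_equal(nrow(mo$annotations), nrow(expected))
    if (nrow(mo$annotations) < 8) dropped <- TRUE
  }
  expect_true(dropped)
})

test_that("brightness adjustment scales and clips", {
  img <- array(100, c(8, 8, 3))
  expect_identical(adjust_brightness(img, 1), img)
  expect_equal(adjust_brightness(img, 2), array(200, c(8, 8, 3)))
  expect_equal(adjust_brightness(img, 3), array(255, c(8, 8, 3)))
  expect_error(adjust_brightness(img, 0), "positive")
})

test_that("gaussian noise is seeded and has the requested spread", {
  img <- array(128, c(200, 200, 3))
  expect_identical(add_gaussian_noise(img, 0, 1), img)
  a <- add_gaussian_noise(img, 5, seed = 3)
  b <- add_gaussian_noise(img, 5, seed = 3)
  expect_identical(a, b)
  expect_false(identical(a, add_gaussian_noise(img, 5, seed = 4)))
  # empirical std within 10% (mid-gray, sigma 10: clipping negligible)
  n <- add_gaussian_noise(img, 10, seed = 5)
  expect_lt(abs(stats::sd(n - img) - 10) / 10, 0.1)
  expect_error(add_gaussian_noise(img, -1, 1), "nonnegative")
})

test_that("k-means anchors handle degenerate and exact cases", {
  same <- tibble::tibble(w = rep(40, 20), h = rep(30, 20))
  expect_warning(anc <- kmeans_anchors(same, k = 9, seed = 1), "degenerate")
  expect_true(all(anc$w == 40 & anc$h == 30))
  nine <- tibble::tibble(w = seq(10, 90, 10), h = seq(90, 10, -10))
  exact <- kmeans_anchors(nine, k = 9, seed = 2)
  expect_lt(attr(exact, "objective"), 1e-12)
  expect_setequal(round(exact$w), nine$w)
  expect_error(kmeans_anchors(nine[1:5, ], k = 9), "at least")
})

test_that("k-means recovers well-separated size modes", {
  withr::with_seed(10, {
    modes <- rbind(c(15, 40), c(60, 20), c(45, 90))
    wh <- do.call(rbind, lapply(1:3, function(m) {
      cbind(w = rnorm(70, modes[m, 1], 0.8), h = rnorm(70, modes[m, 2], 0.8))
    }))
  })
  cl <- kmeans_anchors(tibble::as_tibble(as.data.frame(wh)), k = 3, seed = 3)
  got <- as.matrix(cl[, c("w", "h")])
  ord <- order(got[, 1] * got[, 2])
  want <- modes[order(modes[, 1] * modes[, 2]), ]
  expect_lt(max(abs(got[ord, ] - want) / want), 0.05)
  # exhaustive-restart oracle: many independent restarts cannot beat the
  # returned objective by more than numerical slack
  oracle <- kmeans_anchors(tibble::as_tibble(as.data.frame(wh)), k = 3,
                           seed = 99, restarts = 50)
  expect_lt(attr(cl, "objective") - attr(oracle, "objective"), 1e-6)
  # objective trace is non-increasing within the winning run
  tr <- attr(cl, "trace")
  expect_true(all(diff(tr) <= 1e-12))
})

test_that("anchor scale assignment partitions by ascending area", {
  wh <- cbind(w = 1:9, h = rep(1, 9))   # areas 1..9
  a <- assign_anchor_scales(wh)
  expect_equal(a$scale, rep(1:3, each = 3))
  expect_equal(a$w, 1:9)
  # equal areas: stable order by w then h
  eq <- cbind(w = c(4, 2, 1, 8, 2, 4, 1, 8, 16), h = c(4, 8, 16, 2, 8, 4, 16, 2, 1))
  ae <- assign_anchor_scales(eq)
  expect_equal(ae$w, sort(eq[, 1]))
  expect_error(assign_anchor_scales(wh[1:8, ]), "exactly 9")
  # scale groups are a true partition: 3 + 3 + 3
  expect_equal(as.vector(table(a$scale)), c(3L, 3L, 3L))
})

test_that("the printed prior centers place (46,27) in the smallest-area triplet", {
  centers <- matrix(c(12, 72, 46, 27, 16, 81, 21, 76, 44, 39, 28, 63,
                      20, 97, 41, 58, 35, 79), ncol = 2, byrow = TRUE)
  a <- assign_anchor_scales(centers)
  small <- a[a$scale == 1, ]
  expect_true(any(small$w == 46 & small$h == 27))
})

test_that("euclidean distance mode is available for comparison", {
  wh <- random_boxes(60, seed = 8)[, c("w", "h")]
  anc <- kmeans_anchors(wh, k = 9, seed = 1, distance = "euclidean")
  expect_s3_class(anc, "anchor_set")
  expect_true(all(anc$w > 0))
})
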