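# Greedy matching, PR curves, AP and F1.

det_tbl <- function(ann, score = NULL, jitter = 0) {
  tibble::tibble(cx = ann$cx + jitter, cy = ann$cy, w = ann$w, h = ann$h,
                 score = score %||% rep(1, nrow(ann)), class_index = 0L)
}

test_that("greedy matching handles the canonical cases", {
  ann <- random_annotations(4, seed = 5)
  perfect <- match_detections(det_tbl(ann), ann)
  expect_true(all(perfect$tp))
  expect_equal(attr(perfect, "fn"), 0)
  none <- match_detections(det_tbl(ann[0, ]), ann)
  expect_equal(attr(none, "fn"), 4)
  # two detections on one gt: higher score TP, lower FP
  g <- ann[1, ]
  d2 <- det_tbl(dplyr::bind_rows(g, g), score = c(0.6, 0.9), jitter = 0.5)
  m <- match_detections(d2, g)
  expect_equal(m$tp, c(TRUE, FALSE))       # processed in score order
  expect_equal(m$score, c(0.9, 0.6))
  expect_error(match_detections(d2, g, iou_threshold = 0), "\\(0, 1\\]")
})

test_that("matching agrees with the greedy protocol on small brute-forced cases", {
  for (seed in 1:5) {
    gt <- random_annotations(3, seed = seed)
    det <- det_tbl(dplyr::bind_rows(gt, gt[1:2, ]),
                   score = withr::with_seed(seed, runif(5)), jitter = 2)
    got <- match_detections(det, gt)
    # brute protocol: walk ranked detections, claim best unclaimed gt
    ord <- order(-det$score, -(det$w * det$h), det$cx, det$cy, det$w, det$h)
    claimed <- rep(FALSE, nrow(gt))
    want <- logical(nrow(det))
    for (i in seq_along(ord)) {
      ious <- vapply(seq_len(nrow(gt)), function(j) {
        iou(det[ord[i], , drop = FALSE], gt[j, , drop = FALSE])
      }, numeric(1))
      ious[claimed] <- -1
      j <- which.max(ious)
      if (ious[j] >= 0.5) { want[i] <- TRUE; claimed[j] <- TRUE }
    }
    expect_equal(got$tp, want)
  }
})

test_that("the worked ranked list gives AP = 5/9 with the stated PR points", {
  rep <- pr_curve_and_ap(c(TRUE, FALSE, TRUE), n_gt = 3)
  expect_equal(rep$pr_curve$recall, c(1 / 3, 1 / 3, 2 / 3))
  expect_equal(rep$pr_curve$precision, c(1, 1 / 2, 2 / 3))
  expect_equal(rep$ap50, 5 / 9)
})

test_that("AP equals the rectangle-sum oracle for every flag pattern up to length 8", {
  for (L in 1:8) {
    for (bits in 0:(2^L - 1)) {
      flags <- as.logical(bitwAnd(bits, 2^(0:(L - 1))) > 0)
      n_gt <- max(sum(flags), 1) + (bits %% 2)
      expect_equal(pr_curve_and_ap(flags, n_gt)$ap50, ap_oracle(flags, n_gt))
    }
  }
})

test_that("perfect and empty rankings give the boundary reports", {
  ann <- random_annotations(5, seed = 6)
  all_tp <- pr_curve_and_ap(rep(TRUE, 5), 5)
  expect_equal(c(all_tp$precision, all_tp$recall, all_tp$ap50), c(1, 1, 1))
  empty <- pr_curve_and_ap(logical(0), 5)
  expect_equal(c(empty$recall, empty$ap50), c(0, 0))
  expect_warning(z <- pr_curve_and_ap(c(TRUE, FALSE), 0), "convention|undefined")
  expect_equal(z$ap50, 0)
  expect_true(is.na(z$recall))
})

test_that("trailing false positives never increase AP; claiming a missed gt never decreases it", {
  for (seed in 1:8) {
    L <- withr::with_seed(seed, sample(3:7, 1))
    flags <- withr::with_seed(seed + 50, runif(L) > 0.5)
    n_gt <- sum(flags) + 2
    base <- pr_curve_and_ap(flags, n_gt)$ap50
    expect_lte(pr_curve_and_ap(c(flags, FALSE), n_gt)$ap50, base + 1e-12)
    expect_gte(pr_curve_and_ap(c(flags, TRUE), n_gt)$ap50, base - 1e-12)
  }
})

test_that("F1 is the harmonic mean, on either scale", {
  expect_equal(f1_score(0.9, 0.9), 0.9)
  expect_equal(round(f1_score(97.34, 95.33), 2), 96.32)
  expect_warning(z <- f1_score(0, 0), "undefined")
  expect_equal(z, 0)
  # F1 <= (P + R) / 2 with equality iff P == R
  p <- withr::with_seed(7, runif(100)); r <- withr::with_seed(8, runif(100))
  f <- suppressWarnings(f1_score(p, r))
  expect_true(all(f <= (p + r) / 2 + 1e-12))
  expect_equal(f1_score(0.4, 0.4), (0.4 + 0.4) / 2)
})

test_that("an 11-point interpolation mode exists and brackets the envelope", {
  flags <- c(TRUE, FALSE, TRUE, TRUE, FALSE)
  a11 <- pr_curve_and_ap(flags, 4, interpolation = "11-point")$ap50
  expect_gte(a11, 0)
  expect_lte(a11, 1)
})

test_that("evaluate_detections pools images and honours oracle detectors", {
  gts <- lapply(1:3, function(i) random_annotations(3, seed = i + 10))
  oracle <- lapply(gts, det_tbl)
  rep <- evaluate_detections(oracle, gts)
  expect_equal(rep$ap50, 1)
  silent <- lapply(gts, function(g) det_tbl(g[0, ]))
  rep0 <- evaluate_detections(silent, gts)
  expect_equal(c(rep0$ap50, rep0$recall), c(0, 0))
  expect_equal(rep0$fn, 9)
})

test_that("evaluate_model runs the full inference path on a tiny model", {
  scenes <- tiny_scenes(44, 1:2)
  m <- build_model(tiny_model_config(), seed = 1)
  rep <- evaluate_model(m, scenes, suppression_config(), conf_threshold = 0.2)
  expect_s3_class(rep, "eval_report")
  expect_true(rep$ap50 >= 0 && rep$ap50 <= 1)
  expect_error(evaluate_model(m, list()), "empty")
  gl <- glance(rep)
  expect_equal(gl$ap50, rep$ap50)
  td <- tidy(rep)
  expect_named(td, c("recall", "precision"))
})
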