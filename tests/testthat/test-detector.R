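# Coordinate attention, C3CA, model assembly, decoding, parameter accounting.

test_that("ca_attend preserves shape and keeps gates in (0, 1)", {
  blk <- ca_block(16, reduction = 4, seed = 2)
  x <- array(rnorm(12 * 10 * 16), c(12, 10, 16))
  y <- ca_attend(x, blk)
  expect_equal(dim(y), dim(x))
  # gating can only shrink magnitudes: |y| < |x| elementwise where x != 0
  expect_true(all(abs(y) <= abs(x) + 1e-12))
  expect_true(any(abs(y) < abs(x) - 1e-9))
  expect_error(ca_attend(array(1, c(4, 4)), blk), "array")
  expect_error(ca_attend(array(1, c(4, 4, 8)), blk), "channel")
})

test_that("saturated gates make coordinate attention the identity", {
  blk <- ca_block(8, reduction = 2, seed = 3)
  blk$par[["ca.bh"]] <- rep(40, 8)
  blk$par[["ca.bw"]] <- rep(40, 8)
  blk$par[["ca.wh"]][] <- 0
  blk$par[["ca.ww"]][] <- 0
  x <- array(rnorm(6 * 6 * 8), c(6, 6, 8))
  expect_equal(ca_attend(x, blk), x, tolerance = 1e-5)
})

test_that("spatially constant input yields constant gates matching a hand reference", {
  blk <- ca_block(6, reduction = 2, seed = 4)
  H <- 7; W <- 5
  ch_vals <- rnorm(6)
  x <- aperm(array(rep(ch_vals, each = H * W), c(H, W, 6)), c(1, 2, 3))
  y <- ca_attend(x, blk)
  # hand-rolled reference of the two pooled paths for constant input:
  # both pooled profiles equal the channel values; shared transform, split,
  # per-direction 1x1 + sigmoid
  silu <- function(z) z / (1 + exp(-z))
  sig <- function(z) 1 / (1 + exp(-z))
  hvec <- silu(as.numeric(ch_vals %*% blk$par[["ca.w1"]]) + blk$par[["ca.b1"]])
  gh <- sig(as.numeric(hvec %*% blk$par[["ca.wh"]]) + blk$par[["ca.bh"]])
  gw <- sig(as.numeric(hvec %*% blk$par[["ca.ww"]]) + blk$par[["ca.bw"]])
  for (c in 1:6) {
    expect_equal(unique(round(as.numeric(y[, , c]), 10)),
                 round(ch_vals[c] * gh[c] * gw[c], 10))
  }
})

test_that("C3CA has strictly fewer parameters than matched C3 and keeps shapes", {
  for (ch in c(32, 64, 128)) {
    c3 <- build_c3(ch, ch, n = 1)
    c3ca <- build_c3ca(ch, ch, n = 1)
    expect_lt(count_parameters(c3ca), count_parameters(c3))
  }
  blk <- build_c3ca(32, 32, n = 1, seed = 5)
  x <- array(rnorm(10 * 10 * 32), c(10, 10, 32))
  expect_equal(dim(block_forward(blk, x)), c(10, 10, 32))
})

test_that("C3CA with saturated gates equals the branch-reduced C3 composition", {
  blk <- build_c3ca(16, 16, n = 1, seed = 6)
  blk$par[["c3ca.ca.bh"]] <- rep(40, 8)
  blk$par[["c3ca.ca.bw"]] <- rep(40, 8)
  blk$par[["c3ca.ca.wh"]][] <- 0
  blk$par[["c3ca.ca.ww"]][] <- 0
  x <- array(rnorm(8 * 8 * 16), c(8, 8, 16))
  got <- block_forward(blk, x)
  # manual composition: cv1 -> bottleneck -> concat with first-half channel
  # split of the input -> cv3 (no CA, no secondary conv)
  P <- blk$par; u <- blk$unit
  a <- fishdet:::fwd_conv(NULL, P, u$cv1, x)
  a <- fishdet:::fwd_unit(NULL, P, u$m[[1]], a)
  b <- x[, , 1:8, drop = FALSE]
  want <- fishdet:::fwd_conv(NULL, P, u$cv3,
                             fishdet:::ag_concat_c(NULL, list(a, b)))
  expect_equal(got, want, tolerance = 1e-5)
})

test_that("model configuration is validated", {
  expect_error(model_config(input_size = 100), "divisible")
  expect_error(model_config(depth_multiple = 0), "positive")
  expect_error(model_config(ca_sites = "stem"), "subset")
})

test_that("tiny model forward emits the three stride grids", {
  m <- build_model(tiny_model_config(), seed = 1)
  x <- array(runif(160 * 160 * 3), c(160, 160, 3))
  hh <- forward_model(m, x)
  expect_equal(lapply(hh, dim),
               list(c(20L, 20L, 18L), c(10L, 10L, 18L), c(5L, 5L, 18L)))
})

test_that("parameter count is invariant to input size and counts scalars", {
  m1 <- build_model(tiny_model_config(input_size = 160L))
  m2 <- build_model(tiny_model_config(input_size = 320L))
  expect_equal(count_parameters(m1), count_parameters(m2))
  # single 1x1 convolution, 3 -> 2 channels, with bias
  st <- fishdet:::new_store()
  fishdet:::new_conv(st, "u", 3L, 2L, 1L)
  expect_equal(sum(lengths(as.list(st))), 8)
  # the ledger agrees with the total
  ms <- model_summary(m1)
  expect_equal(sum(ms$n), count_parameters(m1))
})

test_that("tiny preset parameter count matches an independent per-layer ledger", {
  m <- build_model(tiny_model_config(ca_sites = character(0)))
  # hand ledger: conv+bias params per unit at width 0.125 (channels
  # 8/16/32/64/128), depth gain 1/2/3/1, no CA
  conv_p <- function(ci, co, k) ci * co * k^2 + co
  c3_p <- function(ci, co, n) {
    ch <- co / 2
    conv_p(ci, ch, 1) + conv_p(ci, ch, 1) + conv_p(2 * ch, co, 1) +
      n * (conv_p(ch, ch, 1) + conv_p(ch, ch, 3))
  }
  want <- conv_p(12, 8, 3) +                      # focus stem
    conv_p(8, 16, 3) + c3_p(16, 16, 1) +
    conv_p(16, 32, 3) + c3_p(32, 32, 2) +
    conv_p(32, 64, 3) + c3_p(64, 64, 3) +
    conv_p(64, 128, 3) + c3_p(128, 128, 1) +
    conv_p(128, 64, 1) + conv_p(256, 128, 1) +    # sppf cv1, cv2
    conv_p(128, 64, 1) + c3_p(128, 64, 1) +       # nv1, c3_n1
    conv_p(64, 32, 1) + c3_p(64, 32, 1) +         # nv2, c3_n2
    conv_p(32, 32, 3) + c3_p(64, 64, 1) +         # nd1, c3_n3
    conv_p(64, 64, 3) + c3_p(128, 128, 1) +       # nd2, c3_n4
    conv_p(32, 18, 1) + conv_p(64, 18, 1) + conv_p(128, 18, 1)
  expect_equal(count_parameters(m), want)
})

test_that("zero raw logits decode to cell centers at anchor size", {
  anc <- default_anchors(160L)
  raw <- list(array(0, c(20, 20, 18)), array(0, c(10, 10, 18)),
              array(0, c(5, 5, 18)))
  det <- decode_predictions(raw, anc, 160L, conf_threshold = 0)
  expect_equal(nrow(det), 3 * (400 + 100 + 25))
  a1 <- det[abs(det$w - anc$w[1]) < 1e-9, ]
  expect_equal(nrow(a1), 400)
  expect_true(all(abs((a1$cx - 4) %% 8) < 1e-9))   # cell centers at stride 8
  expect_true(all(det$score > 0 & det$score < 1))
  expect_error(decode_predictions(raw[1:2], anc, 160L), "per stride")
  expect_error(decode_predictions(list(raw[[2]], raw[[2]], raw[[3]]), anc, 160L),
               "shape|expected")
})

test_that("decode inverts the target encoding within 1e-6", {
  anc <- default_anchors(160L)
  box <- tibble::tibble(cx = 83.2, cy = 41.7, w = 21.5, h = 33.1)
  tv <- fishdet:::encode_box(box, c(anc$w[5], anc$h[5]), gi = 5, gj = 2,
                             stride = 16)
  raw <- list(array(0, c(20, 20, 18)), array(-20, c(10, 10, 18)),
              array(0, c(5, 5, 18)))
  raw[[2]][3, 6, 7:10] <- tv
  raw[[2]][3, 6, 11:12] <- 50   # objectness and class score
  det <- decode_predictions(raw, anc, 160L, conf_threshold = 0.4)
  det <- det[which.max(det$score), ]
  expect_equal(unlist(det[1, c("cx", "cy", "w", "h")]),
               c(cx = 83.2, cy = 41.7, w = 21.5, h = 33.1), tolerance = 1e-6)
})

test_that("decoded boxes are clipped to the image", {
  anc <- default_anchors(160L)
  raw <- list(array(8, c(20, 20, 18)), array(8, c(10, 10, 18)),
              array(8, c(5, 5, 18)))
  det <- decode_predictions(raw, anc, 160L, conf_threshold = 0)
  cc <- convert_box(det[, c("cx", "cy", "w", "h")], "corner-pixel")
  expect_true(all(cc$xmin >= 0 & cc$xmax <= 160 & cc$ymin >= 0 & cc$ymax <= 160))
})

test_that("the network is translation-consistent at stride granularity", {
  m <- build_model(tiny_model_config(), seed = 5)
  mkimg <- function(x0) {
    px <- array(30, c(160, 160, 3))
    px[71:90, (x0 + 1):(x0 + 14), ] <- 180
    px
  }
  resp <- function(px) forward_model(m, px / 255)[[1]][, , 5]
  r1 <- resp(mkimg(64))
  r2 <- resp(mkimg(72))      # one P3 stride to the right
  # interior response maps agree after a one-cell shift
  expect_lt(max(abs(r1[5:16, 5:15] - r2[5:16, 6:16])), 1e-3)
  band <- 9:12               # rows covering the stimulus
  expect_equal(which.max(r2[band, ]) - which.max(r1[band, ]), length(band))
})

test_that("full-size forward emits 80/40/20 grids on a 640 input", {
  m <- build_model(model_config(ca_sites = character(0)), seed = 1)
  x <- withr::with_seed(9, array(runif(640 * 640 * 3), c(640, 640, 3)))
  hh <- forward_model(m, x)
  expect_equal(lapply(hh, dim),
               list(c(80L, 80L, 18L), c(40L, 40L, 18L), c(20L, 20L, 18L)))
})
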