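# The detector network: Focus stem, CSP (C3 / C3CA) backbone, SPPF,
# FPN+PAN neck with optional coordinate-attention blocks, and three 1x1
# prediction heads at strides 8/16/32.
#
# Convolutions carry a bias and no separate normalization layer: the network
# is built directly in its inference (batch-norm-folded) form, which is both
# the form whose parameter count detection toolchains report and the easiest
# form to train from scratch at desk scale.  All parameters live in a flat
# named list (model$par); layer specs reference them by name.

#' Model configuration
#'
#' Describes the detector variant to build: class count, depth/width
#' multiples of the compound-scaled architecture, input resolution, prior
#' boxes, and where coordinate attention (CA) is inserted.
#'
#' @param num_classes number of object classes (default 1: "fish").
#' @param depth_multiple multiplier on the number of bottleneck repeats.
#' @param width_multiple multiplier on channel widths.
#' @param input_size training/inference resolution in pixels (multiple of 32).
#' @param anchors an anchor set as returned by [kmeans_anchors()] /
#'   [assign_anchor_scales()], or `NULL` for the package default (the nine
#'   tank-fish priors at 640 px reference resolution).
#' @param ca_reduction channel reduction ratio inside CA blocks.
#' @param ca_sites character vector of CA insertion sites, a subset of
#'   `c("backbone_c3", "neck")`.  Empty means the unmodified baseline.
#' @return a `model_config` list.
#' @export
model_config <- function(num_classes = 1L,
                         depth_multiple = 0.33,
                         width_multiple = 0.50,
                         input_size = 640L,
                         anchors = NULL,
                         ca_reduction = 32L,
                         ca_sites = character(0)) {
  validate_that(depth_multiple > 0 && width_multiple > 0,
                "depth_multiple and width_multiple must be positive")
  validate_that(input_size %% 32 == 0,
                "input_size must be divisible by 32 (the largest stride)")
  validate_that(ca_reduction >= 1, "ca_reduction must be >= 1")
  validate_that(all(ca_sites %in% c("backbone_c3", "neck")),
                "ca_sites must be a subset of c('backbone_c3', 'neck')")
  if (is.null(anchors)) anchors <- default_anchors(input_size)
  structure(list(num_classes = as.integer(num_classes),
                 depth_multiple = depth_multiple,
                 width_multiple = width_multiple,
                 input_size = as.integer(input_size),
                 anchors = anchors,
                 ca_reduction = as.integer(ca_reduction),
                 ca_sites = ca_sites),
            class = "model_config")
}

#' Tiny CPU preset of the model configuration
#'
#' A narrow (width 0.125) low-resolution (160 px) variant of the same
#' architecture, intended for CPU smoke training and tests.
#'
#' @param ... overrides passed on to [model_config()].
#' @export
tiny_model_config <- function(...) {
  args <- list(...)
  defaults <- list(width_multiple = 0.125, input_size = 160L,
                   ca_sites = c("backbone_c3", "neck"))
  args <- utils::modifyList(defaults, args)
  do.call(model_config, args)
}

## ---- unit constructors ------------------------------------------------------

new_store <- function() new.env(parent = emptyenv())

put_par <- function(store, name, val) {
  store[[name]] <- val
  name
}

he_init <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
        dim = c(k, k, cin, cout))
}

new_conv <- function(store, name, cin, cout, k = 1L, s = 1L, act = TRUE) {
  list(type = "conv", k = as.integer(k), s = as.integer(s), act = act,
       cin = cin, cout = cout,
       w = put_par(store, paste0(name, ".w"), he_init(k, cin, cout)),
       b = put_par(store, paste0(name, ".b"), numeric(cout)))
}

new_focus <- function(store, name, cin, cout) {
  list(type = "focus", conv = new_conv(store, name, 4L * cin, cout, k = 3L))
}

new_bottleneck <- function(store, name, c, shortcut = TRUE) {
  list(type = "bneck", shortcut = shortcut,
       cv1 = new_conv(store, paste0(name, ".cv1"), c, c, 1L),
       cv2 = new_conv(store, paste0(name, ".cv2"), c, c, 3L))
}

new_c3 <- function(store, name, cin, cout, n, shortcut = TRUE) {
  ch <- cout %/% 2L
  list(type = "c3",
       cv1 = new_conv(store, paste0(name, ".cv1"), cin, ch, 1L),
       cv2 = new_conv(store, paste0(name, ".cv2"), cin, ch, 1L),
       cv3 = new_conv(store, paste0(name, ".cv3"), 2L * ch, cout, 1L),
       m = lapply(seq_len(n), function(i) {
         new_bottleneck(store, paste0(name, ".m", i), ch, shortcut)
       }))
}

new_ca <- function(store, name, c, reduction) {
  cr <- max(8L, c %/% reduction)
  list(type = "ca", c = c, cr = cr,
       w1 = put_par(store, paste0(name, ".w1"),
                    matrix(rnorm(c * cr, sd = sqrt(2 / c)), c, cr)),
       b1 = put_par(store, paste0(name, ".b1"), numeric(cr)),
       wh = put_par(store, paste0(name, ".wh"),
                    matrix(rnorm(cr * c, sd = sqrt(1 / cr)), cr, c)),
       bh = put_par(store, paste0(name, ".bh"), numeric(c)),
       ww = put_par(store, paste0(name, ".ww"),
                    matrix(rnorm(cr * c, sd = sqrt(1 / cr)), cr, c)),
       bw = put_par(store, paste0(name, ".bw"), numeric(c)))
}

# C3 with coordinate attention on the bottleneck branch and the 1x1
# conv-(norm)-activation unit of the secondary branch removed: that branch
# becomes a plain channel split (the first cout/2 input channels pass
# through untouched), so the block strictly saves the secondary 1x1 conv
# at the cost of the small CA weights.
new_c3ca <- function(store, name, cin, cout, n, reduction, shortcut = TRUE) {
  ch <- cout %/% 2L
  stopifnot(cin >= ch)
  list(type = "c3ca", split = ch,
       cv1 = new_conv(store, paste0(name, ".cv1"), cin, ch, 1L),
       m = lapply(seq_len(n), function(i) {
         new_bottleneck(store, paste0(name, ".m", i), ch, shortcut)
       }),
       ca = new_ca(store, paste0(name, ".ca"), ch, reduction),
       cv3 = new_conv(store, paste0(name, ".cv3"), 2L * ch, cout, 1L))
}

new_sppf <- function(store, name, cin, cout, k = 5L) {
  ch <- cin %/% 2L
  list(type = "sppf", k = as.integer(k),
       cv1 = new_conv(store, paste0(name, ".cv1"), cin, ch, 1L),
       cv2 = new_conv(store, paste0(name, ".cv2"), 4L * ch, cout, 1L))
}

new_detect <- function(store, name, cins, num_classes) {
  no <- 3L * (5L + num_classes)
  convs <- lapply(seq_along(cins), function(i) {
    u <- new_conv(store, paste0(name, ".p", i + 2L), cins[i], no, 1L, act = FALSE)
    # objectness prior: start heads believing almost everything is background
    b <- store[[u$b]]
    obj_idx <- 5L + (0:2) * (5L + num_classes)
    b[obj_idx] <- logit_(0.01)
    store[[u$b]] <- b
    u
  })
  list(type = "detect", convs = convs, no = no)
}

## ---- forward passes ---------------------------------------------------------

fwd_conv <- function(tape, P, u, x) {
  y <- ag_conv2d(tape, x, P[[u$w]], P[[u$b]], stride = u$s)
  if (u$act) y <- ag_silu(tape, y) else y
}

fwd_ca <- function(tape, P, u, x) {
  d <- dim(vv(x))
  H <- d[1]; W <- d[2]
  ph <- ag_meanpool_w(tape, x)                      # (H, C)
  pw <- ag_meanpool_h(tape, x)                      # (W, C)
  y <- ag_rbind2(tape, ph, pw)                      # (H + W, C)
  y <- ag_bias_cols(tape, ag_matmul(tape, y, P[[u$w1]]), P[[u$b1]])
  y <- ag_silu(tape, y)
  yh <- ag_rows(tape, y, seq_len(H))
  yw <- ag_rows(tape, y, H + seq_len(W))
  gh <- ag_sigmoid(tape, ag_bias_cols(tape, ag_matmul(tape, yh, P[[u$wh]]), P[[u$bh]]))
  gw <- ag_sigmoid(tape, ag_bias_cols(tape, ag_matmul(tape, yw, P[[u$ww]]), P[[u$bw]]))
  ag_gate_hw(tape, x, gh, gw)
}

fwd_unit <- function(tape, P, u, x) {
  switch(u$type,
    conv = fwd_conv(tape, P, u, x),
    focus = fwd_conv(tape, P, u$conv, ag_focus_slice(tape, x)),
    bneck = {
      y <- fwd_conv(tape, P, u$cv2, fwd_conv(tape, P, u$cv1, x))
      if (u$shortcut) ag_add(tape, x, y) else y
    },
    c3 = {
      a <- fwd_conv(tape, P, u$cv1, x)
      for (bn in u$m) a <- fwd_unit(tape, P, bn, a)
      b <- fwd_conv(tape, P, u$cv2, x)
      fwd_conv(tape, P, u$cv3, ag_concat_c(tape, list(a, b)))
    },
    c3ca = {
      a <- fwd_conv(tape, P, u$cv1, x)
      for (bn in u$m) a <- fwd_unit(tape, P, bn, a)
      a <- fwd_ca(tape, P, u$ca, a)
      b <- ag_channels(tape, x, seq_len(u$split))
      fwd_conv(tape, P, u$cv3, ag_concat_c(tape, list(a, b)))
    },
    ca = fwd_ca(tape, P, u, x),
    sppf = {
      y <- fwd_conv(tape, P, u$cv1, x)
      m1 <- ag_maxpool(tape, y, u$k)
      m2 <- ag_maxpool(tape, m1, u$k)
      m3 <- ag_maxpool(tape, m2, u$k)
      fwd_conv(tape, P, u$cv2, ag_concat_c(tape, list(y, m1, m2, m3)))
    },
    stop("unknown unit type: ", u$type))
}

## ---- model ------------------------------------------------------------------

#' Build the detector network
#'
#' Assembles the single-stage detector described by a [model_config()]:
#' pixel-slicing Focus stem, staged CSP backbone (C3 blocks, or C3CA blocks
#' when `"backbone_c3" %in% ca_sites`), SPPF pyramid pooling, FPN top-down +
#' PAN bottom-up neck (with a coordinate-attention block after each of the
#' four neck fusion C3 blocks when `"neck" %in% ca_sites`), and three 1x1
#' prediction heads emitting `3 * (5 + num_classes)` channels at strides
#' 8, 16 and 32.
#'
#' @param config a [model_config()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `yolo_model`.
#' @export
build_model <- function(config = model_config(), seed = 0L) {
  stopifnot(inherits(config, "model_config"))
  withr::with_seed(as.integer(seed), build_model_impl(config))
}

build_model_impl <- function(config) {
  gw <- config$width_multiple
  gd <- config$depth_multiple
  ch <- function(base) make_divisible(base * gw, 8L)
  n3 <- depth_gain(3L, gd)
  n6 <- depth_gain(6L, gd)
  n9 <- depth_gain(9L, gd)
  ca_bb <- "backbone_c3" %in% config$ca_sites
  ca_nk <- "neck" %in% config$ca_sites
  red <- config$ca_reduction
  st <- new_store()
  bb_c3 <- function(name, cin, cout, n) {
    if (ca_bb) new_c3ca(st, name, cin, cout, n, red) else new_c3(st, name, cin, cout, n)
  }
  L <- list()
  L$stem  <- new_focus(st, "stem", 3L, ch(64))
  L$d1    <- new_conv(st, "d1", ch(64), ch(128), 3L, 2L)
  L$c3_1  <- bb_c3("c3_1", ch(128), ch(128), n3)
  L$d2    <- new_conv(st, "d2", ch(128), ch(256), 3L, 2L)
  L$c3_2  <- bb_c3("c3_2", ch(256), ch(256), n6)
  L$d3    <- new_conv(st, "d3", ch(256), ch(512), 3L, 2L)
  L$c3_3  <- bb_c3("c3_3", ch(512), ch(512), n9)
  L$d4    <- new_conv(st, "d4", ch(512), ch(1024), 3L, 2L)
  L$c3_4  <- bb_c3("c3_4", ch(1024), ch(1024), n3)
  L$sppf  <- new_sppf(st, "sppf", ch(1024), ch(1024))
  L$nv1   <- new_conv(st, "nv1", ch(1024), ch(512), 1L)
  L$c3_n1 <- new_c3(st, "c3_n1", 2L * ch(512), ch(512), n3, shortcut = FALSE)
  L$nv2   <- new_conv(st, "nv2", ch(512), ch(256), 1L)
  L$c3_n2 <- new_c3(st, "c3_n2", 2L * ch(256), ch(256), n3, shortcut = FALSE)
  L$nd1   <- new_conv(st, "nd1", ch(256), ch(256), 3L, 2L)
  L$c3_n3 <- new_c3(st, "c3_n3", 2L * ch(256), ch(512), n3, shortcut = FALSE)
  L$nd2   <- new_conv(st, "nd2", ch(512), ch(512), 3L, 2L)
  L$c3_n4 <- new_c3(st, "c3_n4", 2L * ch(512), ch(1024), n3, shortcut = FALSE)
  if (ca_nk) {
    L$ca_n1 <- new_ca(st, "ca_n1", ch(512), red)
    L$ca_n2 <- new_ca(st, "ca_n2", ch(256), red)
    L$ca_n3 <- new_ca(st, "ca_n3", ch(512), red)
    L$ca_n4 <- new_ca(st, "ca_n4", ch(1024), red)
  }
  L$detect <- new_detect(st, "detect", c(ch(256), ch(512), ch(1024)),
                         config$num_classes)
  structure(list(config = config, layers = L,
                 par = as.list(st), strides = c(8L, 16L, 32L)),
            class = "yolo_model")
}

#' Forward pass of the detector
#'
#' @param model a `yolo_model`.
#' @param x input image as an (H, W, 3) array with values in `[0, 1]`.
#' @param tape internal autodiff tape (leave `NULL` for inference).
#' @param P internal parameter lookup (leave `NULL`).
#' @return list of three raw prediction grids `(K, K, 3 * (5 + num_classes))`
#'   at strides 8, 16, 32.
#' @export
forward_model <- function(model, x, tape = NULL, P = NULL) {
  L <- model$layers
  if (is.null(P)) P <- model$par
  f <- function(u, x) fwd_unit(tape, P, u, x)
  y <- f(L$stem, x)
  y <- f(L$d1, y);  y <- f(L$c3_1, y)
  y <- f(L$d2, y);  p3s <- f(L$c3_2, y)
  y <- f(L$d3, p3s); p4s <- f(L$c3_3, y)
  y <- f(L$d4, p4s); y <- f(L$c3_4, y)
  y <- f(L$sppf, y)
  t1 <- f(L$nv1, y)
  y <- ag_concat_c(tape, list(ag_upsample2x(tape, t1), p4s))
  y <- f(L$c3_n1, y)
  if (!is.null(L$ca_n1)) y <- f(L$ca_n1, y)
  t2 <- f(L$nv2, y)
  y <- ag_concat_c(tape, list(ag_upsample2x(tape, t2), p3s))
  p3 <- f(L$c3_n2, y)
  if (!is.null(L$ca_n2)) p3 <- f(L$ca_n2, p3)
  y <- ag_concat_c(tape, list(f(L$nd1, p3), t2))
  p4 <- f(L$c3_n3, y)
  if (!is.null(L$ca_n3)) p4 <- f(L$ca_n3, p4)
  y <- ag_concat_c(tape, list(f(L$nd2, p4), t1))
  p5 <- f(L$c3_n4, y)
  if (!is.null(L$ca_n4)) p5 <- f(L$ca_n4, p5)
  hd <- L$detect$convs
  list(fwd_conv(tape, P, hd[[1]], p3),
       fwd_conv(tape, P, hd[[2]], p4),
       fwd_conv(tape, P, hd[[3]], p5))
}

#' Count trainable parameters
#'
#' Sum of the lengths of every weight and bias array in the model (the
#' network carries no normalization parameters, so this is also the count a
#' fused inference summary would report).
#'
#' @param model a `yolo_model`, or any unit/list holding parameter arrays.
#' @return integer scalar.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$par, length, numeric(1)))
}

#' Per-layer parameter ledger
#'
#' @param model a `yolo_model`.
#' @return a tibble with one row per named parameter array.
#' @export
model_summary <- function(model) {
  nm <- names(model$par)
  tibble::tibble(
    parameter = nm,
    layer = sub("\\.[wb][1hw]?$", "", nm),
    shape = vapply(model$par, function(p) {
      paste(dim(p) %||% length(p), collapse = "x")
    }, character(1)),
    n = vapply(model$par, length, numeric(1))
  )
}

## ---- standalone blocks (exported for direct use / inspection) ---------------

#' Create a standalone coordinate-attention block
#'
#' @param channels number of feature channels the block operates on.
#' @param reduction channel reduction ratio (hidden width is
#'   `max(8, channels %/% reduction)`).
#' @param seed seed for weight initialization.
#' @return a `ca_block` holding the block's weights.
#' @export
ca_block <- function(channels, reduction = 32L, seed = 0L) {
  st <- new_store()
  u <- withr::with_seed(as.integer(seed),
                        new_ca(st, "ca", as.integer(channels), as.integer(reduction)))
  structure(list(unit = u, par = as.list(st)), class = "ca_block")
}

#' Apply coordinate attention to a feature map
#'
#' Pools the feature map separately along width and height, passes the two
#' pooled profiles through a shared 1x1 transform with a nonlinearity,
#' then produces per-(row, channel) and per-(column, channel) sigmoid gates
#' that rescale the input: `out = x * g_h * g_w` (broadcast).  The output
#' always has the shape of the input.
#'
#' @param x feature map, an (H, W, C) array.
#' @param block a [ca_block()] with matching channel count.
#' @return array of the same shape as `x`.
#' @export
ca_attend <- function(x, block) {
  validate_that(length(dim(x)) == 3, "ca_attend expects an (H, W, C) array")
  validate_that(dim(x)[3] == block$unit$c,
                "channel count of x does not match the block")
  fwd_ca(NULL, block$par, block$unit, x)
}

#' Create a standalone C3 or C3CA block
#'
#' `build_c3()` is the standard CSP bottleneck block; `build_c3ca()` is the
#' modified block in which the bottleneck branch output passes through
#' coordinate attention before fusion and the secondary branch's
#' conv-(norm)-activation unit is removed (the raw input joins the fusion
#' concat directly).  For matched channel counts the C3CA block has strictly
#' fewer parameters.
#'
#' @param cin,cout input/output channel counts.
#' @param n number of bottlenecks.
#' @param reduction CA reduction ratio (C3CA only).
#' @param seed seed for weight initialization.
#' @return a `conv_block`; apply it with [block_forward()], count its
#'   parameters with [count_parameters()].
#' @export
build_c3 <- function(cin, cout, n = 1L, seed = 0L) {
  st <- new_store()
  u <- withr::with_seed(as.integer(seed),
                        new_c3(st, "c3", as.integer(cin), as.integer(cout), as.integer(n)))
  structure(list(unit = u, par = as.list(st)), class = "conv_block")
}

#' @rdname build_c3
#' @export
build_c3ca <- function(cin, cout, n = 1L, reduction = 32L, seed = 0L) {
  st <- new_store()
  u <- withr::with_seed(as.integer(seed),
                        new_c3ca(st, "c3ca", as.integer(cin), as.integer(cout),
                                 as.integer(n), as.integer(reduction)))
  structure(list(unit = u, par = as.list(st)), class = "conv_block")
}

#' Apply a standalone block to a feature map
#'
#' @param block a `conv_block` from [build_c3()] / [build_c3ca()].
#' @param x an (H, W, C) array.
#' @return the block output array.
#' @export
block_forward <- function(block, x) {
  fwd_unit(NULL, block$par, block$unit, x)
}
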