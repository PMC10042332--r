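# The composite training objective: CIoU box regression, objectness binary
# cross-entropy with a no-object penalty weight, and per-class BCE, plus the
# anchor/cell target-assignment rule that decides which grid positions are
# responsible for which ground-truth box.

#' Loss configuration
#'
#' @param lambda_noobj penalty weight on the no-object confidence term.
#' @param box_gain,cfd_gain,cls_gain scale factors on the three components.
#' @param ratio_threshold positive-match threshold: a ground-truth box can
#'   match an anchor only if `max(w/aw, aw/w, h/ah, ah/h)` is below this.
#' @param scale_balance per-scale multipliers on the confidence term
#'   (P3/P4/P5); fine heads see many more positions, coarse heads produce
#'   the least precise boxes, so the conventional weighting boosts P3 and
#'   damps P5.
#' @param iou_obj_target if `TRUE`, the objectness target at a positive
#'   position is the (detached) CIoU-free IoU of the currently decoded box
#'   with its ground truth instead of the constant 1, calibrating scores by
#'   localization quality.
#' @return a `loss_config` list.
#' @export
loss_config <- function(lambda_noobj = 0.5, box_gain = 10, cfd_gain = 1,
                        cls_gain = 1, ratio_threshold = 4,
                        scale_balance = c(4, 1, 0.4), iou_obj_target = TRUE) {
  validate_that(lambda_noobj >= 0, "lambda_noobj must be nonnegative")
  validate_that(length(scale_balance) == 3 && all(scale_balance > 0),
                "scale_balance needs one positive weight per head")
  structure(list(lambda_noobj = lambda_noobj, box_gain = box_gain,
                 cfd_gain = cfd_gain, cls_gain = cls_gain,
                 ratio_threshold = ratio_threshold,
                 scale_balance = scale_balance,
                 iou_obj_target = isTRUE(iou_obj_target)),
            class = "loss_config")
}

box_corners_mat <- function(b) {
  cbind(xmin = b$cx - b$w / 2, ymin = b$cy - b$h / 2,
        xmax = b$cx + b$w / 2, ymax = b$cy + b$h / 2)
}

check_boxes_valid <- function(b, what) {
  validate_that(all(b$w > 0) && all(b$h > 0),
                paste0("degenerate (zero-area) box in ", what))
}

#' Intersection over union of paired boxes
#'
#' Row-wise IoU of two box tibbles in center-pixel form (single-row inputs
#' recycle against the other argument).
#'
#' @param a,b box tibbles with columns `cx, cy, w, h`.
#' @return numeric vector of IoU values in `[0, 1]` (0 for disjoint pairs).
#' @export
iou <- function(a, b) {
  check_boxes_valid(a, "iou() first argument")
  check_boxes_valid(b, "iou() second argument")
  ca <- box_corners_mat(a); cb <- box_corners_mat(b)
  n <- max(nrow(ca), nrow(cb))
  if (nrow(ca) == 1) ca <- ca[rep(1, n), , drop = FALSE]
  if (nrow(cb) == 1) cb <- cb[rep(1, n), , drop = FALSE]
  iw <- pmax(0, pmin(ca[, 3], cb[, 3]) - pmax(ca[, 1], cb[, 1]))
  ih <- pmax(0, pmin(ca[, 4], cb[, 4]) - pmax(ca[, 2], cb[, 2]))
  inter <- iw * ih
  union <- (ca[, 3] - ca[, 1]) * (ca[, 4] - ca[, 2]) +
    (cb[, 3] - cb[, 1]) * (cb[, 4] - cb[, 2]) - inter
  unname(inter / union)
}

#' Complete IoU (CIoU) of paired boxes
#'
#' `CIoU = IoU - rho^2 / c^2 - alpha * v`, where `rho` is the distance
#' between box centers, `c` the diagonal of the minimum enclosing box,
#' `v = (4 / pi^2) * (atan(w_gt / h_gt) - atan(w / h))^2` the aspect-ratio
#' penalty and `alpha = v / ((1 - IoU) + v)`.  Equal to IoU exactly for
#' concentric boxes of equal aspect ratio and to 1 only for identical boxes.
#'
#' @param pred,gt box tibbles with columns `cx, cy, w, h` (row-wise pairs;
#'   single rows recycle).
#' @return numeric vector of CIoU values (each `<= 1`).
#' @export
ciou <- function(pred, gt) {
  check_boxes_valid(pred, "ciou() prediction")
  check_boxes_valid(gt, "ciou() ground truth")
  n <- max(nrow(pred), nrow(gt))
  rep1 <- function(b) if (nrow(b) == 1) b[rep(1, n), ] else b
  p <- rep1(pred); g <- rep1(gt)
  i <- iou(p, g)
  rho2 <- (p$cx - g$cx)^2 + (p$cy - g$cy)^2
  cw <- pmax(p$cx + p$w / 2, g$cx + g$w / 2) - pmin(p$cx - p$w / 2, g$cx - g$w / 2)
  chh <- pmax(p$cy + p$h / 2, g$cy + g$h / 2) - pmin(p$cy - p$h / 2, g$cy - g$h / 2)
  c2 <- cw^2 + chh^2
  v <- (4 / pi^2) * (atan(g$w / g$h) - atan(p$w / p$h))^2
  alpha <- v / ((1 - i) + v + 1e-12)
  i - rho2 / pmax(c2, 1e-12) - alpha * v
}

#' Box regression loss over matched pairs
#'
#' Mean of `1 - CIoU` over positive matches; `0` (with a message) when the
#' match set is empty.
#'
#' @inheritParams ciou
#' @return scalar loss `>= 0`.
#' @export
bbox_loss <- function(pred, gt) {
  if (nrow(pred) == 0 || nrow(gt) == 0) {
    rlang::inform("bbox_loss: empty match set, returning 0")
    return(0)
  }
  mean(1 - ciou(pred, gt))
}

bce_prob <- function(p, y) {
  # clamp only inside the logs, so exact predictions give exactly 0
  -(y * log(pmax(p, 1e-7)) + (1 - y) * log(pmax(1 - p, 1e-7)))
}

#' Confidence (objectness) loss
#'
#' Binary cross-entropy of predicted objectness against the assigned target
#' confidence (1 at object positions, 0 elsewhere): the sum over object
#' positions plus `lambda_noobj` times the sum over no-object positions,
#' normalized by the total number of positions (so every grid position
#' carries the same per-position weight and `lambda_noobj` rescales only
#' the background term).
#'
#' @param pred predicted objectness probabilities (any numeric array).
#' @param obj_mask logical array of the same shape: `TRUE` where an object
#'   is assigned.
#' @param lambda_noobj no-object penalty weight.
#' @return scalar loss.
#' @export
confidence_loss <- function(pred, obj_mask, lambda_noobj = 0.5) {
  validate_that(length(pred) == length(obj_mask),
                "pred and obj_mask must have the same shape")
  obj_mask <- as.logical(obj_mask)
  s_obj <- sum(bce_prob(pred[obj_mask], 1))
  s_noobj <- sum(bce_prob(pred[!obj_mask], 0))
  (s_obj + lambda_noobj * s_noobj) / length(pred)
}

#' Classification loss at object positions
#'
#' Per-class binary cross-entropy of the predicted class probabilities
#' against one-hot targets, summed over classes and averaged over object
#' positions (no-object positions do not contribute).
#'
#' @param pred matrix of class probabilities, one row per object position.
#' @param class_index 0-based true class per row.
#' @return scalar loss.
#' @export
class_loss <- function(pred, class_index) {
  pred <- as.matrix(pred)
  if (nrow(pred) == 0) return(0)
  validate_that(all(class_index >= 0 & class_index < ncol(pred)),
                "class index out of range")
  onehot <- matrix(0, nrow(pred), ncol(pred))
  onehot[cbind(seq_len(nrow(pred)), class_index + 1L)] <- 1
  mean(rowSums(bce_prob(pred, onehot)))
}

## ---- target assignment ------------------------------------------------------

#' Assign ground-truth boxes to anchor/cell positions
#'
#' A ground truth is positive for an anchor when
#' `max(w/aw, aw/w, h/ah, ah/h) < ratio_threshold`; it is placed in its
#' containing grid cell plus the two nearest neighbour cells (one along each
#' axis, chosen by which side of the cell center the box center falls on).
#'
#' @param annotations annotation tibble (center-pixel, at `input_size` scale).
#' @param anchors an `anchor_set` (see [kmeans_anchors()]).
#' @param input_size network input resolution in pixels.
#' @param strides the three head strides.
#' @param ratio_threshold positive-match size ratio bound.
#' @param classes class vocabulary giving each annotation its class index.
#' @return tibble of positives: `scale`, `anchor` (1-3 within scale), `gi`,
#'   `gj` (0-based cell column/row), `gt`, the ground-truth box columns and
#'   `class_idx` (0-based).
#' @export
assign_targets <- function(annotations, anchors, input_size,
                           strides = c(8L, 16L, 32L), ratio_threshold = 4,
                           classes = "fish") {
  ann <- annotations
  if (nrow(ann) == 0) return(assign_empty())
  validate_that(all(ann$cx >= 0 & ann$cx <= input_size &
                      ann$cy >= 0 & ann$cy <= input_size),
                "ground-truth box center outside the image")
  am <- anchor_matrix(anchors)
  out <- vector("list", 0L)
  for (s in seq_along(strides)) {
    st <- strides[s]
    K <- input_size %/% st
    asc <- am[am[, "scale"] == s, , drop = FALSE]
    for (g in seq_len(nrow(ann))) {
      fx <- ann$cx[g] / st
      fy <- ann$cy[g] / st
      ci <- floor(fx); cj <- floor(fy)
      cand_i <- c(ci, if (fx - ci < 0.5) ci - 1 else ci + 1, ci)
      cand_j <- c(cj, cj, if (fy - cj < 0.5) cj - 1 else cj + 1)
      keep <- cand_i >= 0 & cand_i < K & cand_j >= 0 & cand_j < K
      cand_i <- cand_i[keep]; cand_j <- cand_j[keep]
      for (a in seq_len(nrow(asc))) {
        r <- max(ann$w[g] / asc[a, "w"], asc[a, "w"] / ann$w[g],
                 ann$h[g] / asc[a, "h"], asc[a, "h"] / ann$h[g])
        if (r < ratio_threshold) {
          out[[length(out) + 1L]] <- tibble::tibble(
            scale = s, anchor = a, gi = cand_i, gj = cand_j, gt = g,
            cx = ann$cx[g], cy = ann$cy[g], w = ann$w[g], h = ann$h[g],
            class_idx = match(ann$class[g], classes) - 1L,
            anchor_w = asc[a, "w"], anchor_h = asc[a, "h"])
        }
      }
    }
  }
  if (length(out) == 0) {
    rlang::warn("no ground-truth box matched any anchor (size ratio threshold)")
    return(assign_empty())
  }
  res <- dplyr::distinct(dplyr::bind_rows(out),
                         .data$scale, .data$anchor, .data$gi, .data$gj, .data$gt,
                         .keep_all = TRUE)
  matched <- unique(res$gt)
  if (length(matched) < nrow(ann)) {
    rlang::warn(sprintf("%d ground-truth box(es) matched no anchor",
                        nrow(ann) - length(matched)))
  }
  res
}

assign_empty <- function() {
  tibble::tibble(scale = integer(), anchor = integer(), gi = numeric(),
                 gj = numeric(), gt = integer(), cx = numeric(), cy = numeric(),
                 w = numeric(), h = numeric(), class_idx = integer(),
                 anchor_w = numeric(), anchor_h = numeric())
}

## ---- autograd composite loss (training path) --------------------------------

# CIoU as autodiff ops; gt columns are constants, alpha is detached.
ciou_nodes <- function(tape, px, py, pw, ph, g) {
  eps <- 1e-9
  x1 <- ag_sub(tape, px, ag_affine(tape, pw, 0.5))
  x2 <- ag_add(tape, px, ag_affine(tape, pw, 0.5))
  y1 <- ag_sub(tape, py, ag_affine(tape, ph, 0.5))
  y2 <- ag_add(tape, py, ag_affine(tape, ph, 0.5))
  gx1 <- g$cx - g$w / 2; gx2 <- g$cx + g$w / 2
  gy1 <- g$cy - g$h / 2; gy2 <- g$cy + g$h / 2
  iw <- ag_pmax_const(tape, ag_sub(tape, ag_pmin_const(tape, x2, gx2),
                                   ag_pmax_const(tape, x1, gx1)), 0)
  ih <- ag_pmax_const(tape, ag_sub(tape, ag_pmin_const(tape, y2, gy2),
                                   ag_pmax_const(tape, y1, gy1)), 0)
  inter <- ag_mul(tape, iw, ih)
  area_p <- ag_mul(tape, pw, ph)
  uni <- ag_add(tape, ag_sub(tape, ag_affine(tape, area_p, 1, g$w * g$h + eps), inter), 0)
  i <- ag_div(tape, inter, uni)
  dx <- ag_sub(tape, px, g$cx)
  dy <- ag_sub(tape, py, g$cy)
  rho2 <- ag_add(tape, ag_square(tape, dx), ag_square(tape, dy))
  cw <- ag_sub(tape, ag_pmax_const(tape, x2, gx2), ag_pmin_const(tape, x1, gx1))
  ch <- ag_sub(tape, ag_pmax_const(tape, y2, gy2), ag_pmin_const(tape, y1, gy1))
  c2 <- ag_affine(tape, ag_add(tape, ag_square(tape, cw), ag_square(tape, ch)), 1, eps)
  ar <- ag_atan(tape, ag_div(tape, pw, ph))
  vterm <- ag_square(tape, ag_affine(tape, ar, -1, atan(g$w / g$h)))
  v <- ag_affine(tape, vterm, 4 / pi^2)
  alpha <- vv(v) / ((1 - vv(i)) + vv(v) + 1e-12)   # detached weight
  ag_sub(tape, ag_sub(tape, i, ag_div(tape, rho2, c2)), ag_mul(tape, v, alpha))
}

# Composite loss on one image's raw head outputs (autodiff nodes or arrays).
# Returns scalar nodes/values for total and components.
detection_loss_nodes <- function(tape, heads, targets, input_size,
                                 strides = c(8L, 16L, 32L), num_classes = 1L,
                                 cfg = loss_config()) {
  nco <- 5L + num_classes
  box_terms <- list()
  cls_terms <- list()
  cfd_sums <- vector("list", length(heads))
  n_pos_total <- sum(targets$scale %in% seq_along(heads))
  n_total <- sum(vapply(heads, function(h) prod(dim(vv(h))[1:2]) * 3, numeric(1)))
  for (s in seq_along(heads)) {
    hd <- heads[[s]]
    d <- dim(vv(hd))
    K <- d[1]
    tg <- targets[targets$scale == s, , drop = FALSE]
    obj_tgt <- array(0, c(K, K, 3))
    if (nrow(tg) > 0) {
      base <- (tg$anchor - 1L) * nco
      lin <- function(ch) (tg$gj + 1) + tg$gi * K + (ch - 1) * K * K
      sel <- cbind(lin(base + 1L), lin(base + 2L), lin(base + 3L), lin(base + 4L))
      raw <- ag_gather(tape, hd, sel)
      st <- strides[s]
      px <- ag_affine(tape, ag_sigmoid(tape, ag_col(tape, raw, 1L)),
                      2 * st, (tg$gi - 0.5) * st)
      py <- ag_affine(tape, ag_sigmoid(tape, ag_col(tape, raw, 2L)),
                      2 * st, (tg$gj - 0.5) * st)
      # floor the decoded sizes: keeps the aspect-ratio term finite when a
      # sigmoid underflows to zero early in training
      pw <- ag_pmax_const(tape, ag_mul(tape, ag_square(tape,
                                   ag_affine(tape, ag_sigmoid(tape, ag_col(tape, raw, 3L)), 2)),
                   tg$anchor_w), 1e-2)
      ph <- ag_pmax_const(tape, ag_mul(tape, ag_square(tape,
                                   ag_affine(tape, ag_sigmoid(tape, ag_col(tape, raw, 4L)), 2)),
                   tg$anchor_h), 1e-2)
      ci <- ciou_nodes(tape, px, py, pw, ph, tg)
      box_terms[[length(box_terms) + 1L]] <-
        ag_sum(tape, ag_affine(tape, ci, -1, 1))
      # objectness target: 1, or the detached IoU of the currently decoded
      # box with its ground truth (score then ranks by localization quality)
      tval <- if (cfg$iou_obj_target) {
        pmax(0.05, iou(tibble::tibble(cx = vv(px), cy = vv(py),
                                      w = pmax(vv(pw), 1e-2), h = pmax(vv(ph), 1e-2)),
                       tg[, c("cx", "cy", "w", "h")]))
      } else {
        rep(1, nrow(tg))
      }
      # array index: row = gj + 1 (y), col = gi + 1 (x), slab = anchor
      obj_tgt[cbind(tg$gj + 1, tg$gi + 1, tg$anchor)] <- tval
      if (num_classes >= 1) {
        sel_cls <- do.call(cbind, lapply(seq_len(num_classes),
                                         function(cc) lin(base + 5L + cc)))
        cls_raw <- ag_gather(tape, hd, sel_cls)
        onehot <- matrix(0, nrow(tg), num_classes)
        onehot[cbind(seq_len(nrow(tg)), tg$class_idx + 1L)] <- 1
        cls_terms[[length(cls_terms) + 1L]] <-
          ag_bce_logits_sum(tape, cls_raw, onehot)
      }
    }
    obj_logits <- ag_channels(tape, hd, 5L + (0:2) * nco)
    # object-position BCE plus lambda_noobj times the no-object BCE, jointly
    # normalized over all positions and balanced per scale
    is_obj <- obj_tgt > 0
    wgt <- cfg$scale_balance[s] * (is_obj + cfg$lambda_noobj * (1 - is_obj)) / n_total
    cfd_sums[[s]] <- ag_bce_logits_sum(tape, obj_logits, obj_tgt, weight = wgt)
  }
  # components carry their configured gains, so total is exactly their sum
  l_cfd <- ag_affine(tape, ag_addn(tape, cfd_sums), cfg$cfd_gain)
  l_bbox <- if (n_pos_total > 0) {
    ag_affine(tape, ag_addn(tape, box_terms), cfg$box_gain / n_pos_total)
  } else 0
  l_cls <- if (n_pos_total > 0) {
    ag_affine(tape, ag_addn(tape, cls_terms), cfg$cls_gain / n_pos_total)
  } else 0
  total <- ag_addn(tape, list(l_bbox, l_cfd, l_cls))
  list(total = total, l_bbox = l_bbox, l_cfd = l_cfd, l_cls = l_cls)
}

#' Evaluate the composite detection loss of one labeled image
#'
#' Forward-only convenience wrapper: runs the model, assigns targets and
#' returns the loss components `l_bbox`, `l_cfd`, `l_cls` and their sum.
#'
#' @param model a `yolo_model`.
#' @param im a [labeled_image()] already at the model's input size.
#' @param cfg a [loss_config()].
#' @param classes class vocabulary.
#' @return named list of numeric loss components.
#' @export
detection_loss <- function(model, im, cfg = loss_config(), classes = "fish") {
  heads <- forward_model(model, im$pixels / 255)
  tg <- suppressWarnings(
    assign_targets(im$annotations, model$config$anchors, model$config$input_size,
                   model$strides, cfg$ratio_threshold, classes))
  out <- detection_loss_nodes(NULL, heads, tg, model$config$input_size,
                              model$strides, model$config$num_classes, cfg)
  lapply(out, as.numeric)
}
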