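# Decoding raw prediction grids into pixel-space detections.

#' Decode raw prediction grids into detections
#'
#' Per cell and anchor: `center = (2 * sigmoid(t_xy) - 0.5 + grid_xy) * stride`,
#' `size = anchor * (2 * sigmoid(t_wh))^2`,
#' `score = sigmoid(t_obj) * max_c sigmoid(t_cls)`.  Boxes are clipped to the
#' image.
#'
#' @param raw list of three raw grids `(K, K, 3 * (5 + num_classes))` from
#'   [forward_model()].
#' @param anchors the model's `anchor_set` (at input resolution).
#' @param input_size input resolution in pixels.
#' @param strides the three head strides.
#' @param num_classes number of classes.
#' @param conf_threshold drop detections scoring below this.
#' @return detections tibble: `cx, cy, w, h, score, class_index` (0-based).
#' @export
decode_predictions <- function(raw, anchors, input_size,
                               strides = c(8L, 16L, 32L), num_classes = 1L,
                               conf_threshold = 0.001) {
  validate_that(length(raw) == length(strides), "one raw grid per stride expected")
  nco <- 5L + num_classes
  am <- anchor_matrix(anchors)
  out <- vector("list", 0L)
  for (s in seq_along(raw)) {
    arr <- raw[[s]]
    K <- input_size %/% strides[s]
    d <- dim(arr)
    validate_that(length(d) == 3 && d[1] == K && d[2] == K && d[3] == 3L * nco,
                  sprintf("raw grid %d has shape %s, expected %dx%dx%d",
                          s, paste(d, collapse = "x"), K, K, 3L * nco))
    asc <- am[am[, "scale"] == s, , drop = FALSE]
    gx <- matrix(rep(0:(K - 1), each = K), K, K)   # column index (x)
    gy <- matrix(rep(0:(K - 1), times = K), K, K)  # row index (y)
    for (a in 1:3) {
      base <- (a - 1L) * nco
      tx <- sigmoid_(arr[, , base + 1L])
      ty <- sigmoid_(arr[, , base + 2L])
      tw <- sigmoid_(arr[, , base + 3L])
      th <- sigmoid_(arr[, , base + 4L])
      obj <- sigmoid_(arr[, , base + 5L])
      cls <- array(sigmoid_(arr[, , base + 5L + seq_len(num_classes)]),
                   dim = c(K, K, num_classes))
      cls_best <- apply(cls, c(1, 2), which.max) - 1L
      cls_p <- apply(cls, c(1, 2), max)
      out[[length(out) + 1L]] <- tibble::tibble(
        cx = as.numeric((2 * tx - 0.5 + gx) * strides[s]),
        cy = as.numeric((2 * ty - 0.5 + gy) * strides[s]),
        w = as.numeric((2 * tw)^2 * asc[a, "w"]),
        h = as.numeric((2 * th)^2 * asc[a, "h"]),
        score = as.numeric(obj * cls_p),
        class_index = as.integer(cls_best))
    }
  }
  det <- dplyr::bind_rows(out)
  # clip to the image
  xmin <- pmax(det$cx - det$w / 2, 0); xmax <- pmin(det$cx + det$w / 2, input_size)
  ymin <- pmax(det$cy - det$h / 2, 0); ymax <- pmin(det$cy + det$h / 2, input_size)
  keep <- xmax > xmin & ymax > ymin & det$score >= conf_threshold
  det$cx <- (xmin + xmax) / 2; det$w <- xmax - xmin
  det$cy <- (ymin + ymax) / 2; det$h <- ymax - ymin
  det[keep, , drop = FALSE]
}

# inverse of the decode mapping, for one positive target (used in tests and
# target diagnostics): returns the raw logits that decode to `box` at the
# given cell/anchor
encode_box <- function(box, anchor_wh, gi, gj, stride) {
  sx <- (box$cx / stride - gi + 0.5) / 2
  sy <- (box$cy / stride - gj + 0.5) / 2
  sw <- sqrt(box$w / anchor_wh[1]) / 2
  sh <- sqrt(box$h / anchor_wh[2]) / 2
  stopifnot(all(c(sx, sy, sw, sh) > 0 & c(sx, sy, sw, sh) < 1))
  c(tx = logit_(sx), ty = logit_(sy), tw = logit_(sw), th = logit_(sh))
}
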