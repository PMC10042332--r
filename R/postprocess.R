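# Prediction-box re-screening: classical greedy NMS and linear Soft-NMS.
#
# Standard orientation: a box is suppressed (NMS) or its score decayed
# (Soft-NMS) when its overlap with the current highest-scoring box EXCEEDS
# the threshold.  `transposed = TRUE` inverts both comparisons (keep/decay
# on overlap at or above the threshold), a variant kept for comparison.

#' Suppression configuration
#'
#' @param nj overlap threshold in `[0, 1]`.
#' @param final_score_min discard rescored boxes below this.
#' @param method `"soft-nms"` or `"nms"`.
#' @return a `suppression_config` list.
#' @export
suppression_config <- function(nj = 0.5, final_score_min = 0.001,
                               method = c("soft-nms", "nms")) {
  validate_that(nj >= 0 && nj <= 1, "nj must lie in [0, 1]")
  validate_that(final_score_min >= 0 && final_score_min < 1,
                "final_score_min must lie in [0, 1)")
  structure(list(nj = nj, final_score_min = final_score_min,
                 method = match.arg(method)),
            class = "suppression_config")
}

# deterministic processing order: score desc, then area desc, then coords
det_order <- function(det) {
  order(-det$score, -(det$w * det$h), det$cx, det$cy, det$w, det$h)
}

# IoU of one box (corner vector) against corner-matrix rows
iou_one <- function(m1, mk) {
  iw <- pmax(0, pmin(m1[3], mk[, 3]) - pmax(m1[1], mk[, 1]))
  ih <- pmax(0, pmin(m1[4], mk[, 4]) - pmax(m1[2], mk[, 2]))
  inter <- iw * ih
  inter / ((m1[3] - m1[1]) * (m1[4] - m1[2]) +
             (mk[, 3] - mk[, 1]) * (mk[, 4] - mk[, 2]) - inter)
}

check_detections <- function(det) {
  validate_that(all(det$score >= 0 & det$score <= 1), "scores must lie in [0, 1]")
  if (is.null(det$class_index)) det$class_index <- 0L
  det
}

#' Non-maximum suppression
#'
#' Greedy per-class suppression: repeatedly emit the highest-scoring box and
#' zero the score of every remaining box whose IoU with it exceeds `nj`.
#'
#' @param detections detections tibble (`cx, cy, w, h, score`, optional
#'   `class_index`).
#' @param nj overlap threshold.
#' @param transposed invert the comparisons (suppress on overlap *below*
#'   the threshold); kept for comparison with the standard rule.
#' @return the kept detections, scores unchanged, sorted by score.
#' @export
nms <- function(detections, nj = 0.5, transposed = FALSE) {
  validate_that(nj >= 0 && nj <= 1, "nj must lie in [0, 1]")
  det <- check_detections(detections)
  if (nrow(det) == 0) return(det)
  parts <- split(seq_len(nrow(det)), det$class_index)
  keep_all <- integer(0)
  for (idx in parts) {
    d <- det[idx, , drop = FALSE]
    ord <- det_order(d)
    mm <- cbind(d$cx - d$w / 2, d$cy - d$h / 2,
                d$cx + d$w / 2, d$cy + d$h / 2)[ord, , drop = FALSE]
    n <- length(ord)
    alive <- rep(TRUE, n)
    for (i in seq_len(n)) {
      if (!alive[i]) next
      rest <- which(alive & seq_len(n) > i)
      if (length(rest)) {
        ov <- iou_one(mm[i, ], mm[rest, , drop = FALSE])
        kill <- if (transposed) ov < nj else ov > nj
        alive[rest[kill]] <- FALSE
      }
    }
    keep_all <- c(keep_all, idx[ord[alive]])
  }
  out <- det[keep_all, , drop = FALSE]
  out[det_order(out), , drop = FALSE]
}

#' Linear Soft-NMS
#'
#' Greedy per-class rescoring: take the current highest-scoring box M, then
#' rescale each remaining score `s_k <- s_k * (1 - IoU(M, b_k))` when the
#' overlap exceeds `nj` (unchanged otherwise); iterate over the remaining
#' boxes; finally discard boxes scoring below `final_score_min`.  Scores
#' never increase and the globally highest-scoring box is always emitted
#' unchanged.
#'
#' @inheritParams nms
#' @param final_score_min discard threshold on the rescored boxes.
#' @return rescored detections, sorted by final score.
#' @export
soft_nms <- function(detections, nj = 0.5, final_score_min = 0.001,
                     transposed = FALSE) {
  validate_that(nj >= 0 && nj <= 1, "nj must lie in [0, 1]")
  det <- check_detections(detections)
  if (nrow(det) == 0) return(det)
  parts <- split(seq_len(nrow(det)), det$class_index)
  pieces <- vector("list", 0L)
  for (idx in parts) {
    d <- det[idx, , drop = FALSE]
    d <- d[det_order(d), , drop = FALSE]
    mm <- cbind(d$cx - d$w / 2, d$cy - d$h / 2,
                d$cx + d$w / 2, d$cy + d$h / 2)
    sc <- d$score
    n <- nrow(d)
    done <- logical(n)
    for (step in seq_len(n)) {
      live <- which(!done)
      if (!length(live)) break
      m <- live[which.max(sc[live])]   # ties: first in deterministic order
      done[m] <- TRUE
      rest <- live[live != m]
      if (length(rest)) {
        ov <- iou_one(mm[m, ], mm[rest, , drop = FALSE])
        decay <- if (transposed) ov < nj else ov > nj
        sc[rest[decay]] <- sc[rest[decay]] * (1 - ov[decay])
      }
    }
    d$score <- sc
    pieces[[length(pieces) + 1L]] <- d[sc >= final_score_min, , drop = FALSE]
  }
  out <- dplyr::bind_rows(pieces)
  out[det_order(out), , drop = FALSE]
}

#' Apply the configured suppression method
#'
#' @param detections detections tibble.
#' @param config a [suppression_config()].
#' @param transposed see [nms()].
#' @export
rescreen <- function(detections, config = suppression_config(),
                     transposed = FALSE) {
  stopifnot(inherits(config, "suppression_config"))
  if (config$method == "nms") {
    out <- nms(detections, config$nj, transposed)
    out[out$score >= config$final_score_min, , drop = FALSE]
  } else {
    soft_nms(detections, config$nj, config$final_score_min, transposed)
  }
}

#' Count fish among post-suppression detections
#'
#' @param detections post-suppression detections tibble.
#' @param score_min count detections with final score at or above this.
#' @param class_index class to count (0 = fish in the default vocabulary).
#' @return integer count.
#' @export
count_fish <- function(detections, score_min = 0.001, class_index = 0L) {
  if (nrow(detections) == 0) return(0L)
  ci <- detections$class_index %||% rep(0L, nrow(detections))
  sum(detections$score >= score_min & ci == class_index)
}
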