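# Detection scoring: greedy matching at an IoU threshold, precision/recall,
# average precision as the area under the PR curve, and F1.

#' Match detections against ground truth
#'
#' Greedy one-to-one protocol: detections are processed in descending score
#' order (deterministic tie-break by score, then area, then coordinates);
#' each claims the still-unclaimed ground-truth box with the highest IoU at
#' or above the threshold (a true positive) or becomes a false positive.
#' Unclaimed ground truths are false negatives.
#'
#' @param detections detections tibble (`cx, cy, w, h, score`).
#' @param ground_truth annotation tibble (`cx, cy, w, h`).
#' @param iou_threshold match threshold in (0, 1].
#' @return the detections in processing order with a logical `tp` column;
#'   attributes `n_gt` and `fn`.
#' @export
match_detections <- function(detections, ground_truth, iou_threshold = 0.5) {
  validate_that(iou_threshold > 0 && iou_threshold <= 1,
                "iou_threshold must lie in (0, 1]")
  det <- detections[det_order(detections), , drop = FALSE]
  n_gt <- nrow(ground_truth)
  tp <- logical(nrow(det))
  claimed <- logical(n_gt)
  if (n_gt > 0 && nrow(det) > 0) {
    gtm <- cbind(ground_truth$cx - ground_truth$w / 2,
                 ground_truth$cy - ground_truth$h / 2,
                 ground_truth$cx + ground_truth$w / 2,
                 ground_truth$cy + ground_truth$h / 2)
    for (i in seq_len(nrow(det))) {
      m1 <- c(det$cx[i] - det$w[i] / 2, det$cy[i] - det$h[i] / 2,
              det$cx[i] + det$w[i] / 2, det$cy[i] + det$h[i] / 2)
      ov <- iou_one(m1, gtm)
      ov[claimed] <- -1
      j <- which.max(ov)
      if (length(j) && ov[j] >= iou_threshold) {
        tp[i] <- TRUE
        claimed[j] <- TRUE
      }
    }
  }
  det$tp <- tp
  attr(det, "n_gt") <- n_gt
  attr(det, "fn") <- n_gt - sum(tp)
  det
}

#' F1 score
#'
#' Harmonic mean `2 P R / (P + R)`; defined as 0 (with a warning) when both
#' precision and recall are 0.  Inputs may be fractions or percentages (the
#' scale carries through).
#'
#' @param precision,recall numeric, same scale.
#' @return numeric F1 on the input scale.
#' @export
f1_score <- function(precision, recall) {
  validate_that(all(precision >= 0) && all(recall >= 0),
                "precision and recall must be nonnegative")
  out <- numeric(length(precision))
  both0 <- precision + recall == 0
  if (any(both0)) rlang::warn("F1 undefined at P = R = 0; returning 0")
  out[!both0] <- 2 * precision[!both0] * recall[!both0] /
    (precision[!both0] + recall[!both0])
  out
}

#' Precision-recall curve, AP and F1 from ranked match flags
#'
#' Computes cumulative precision/recall over the score-ranked detection
#' list, the average precision as the area under the precision envelope
#' (all-point interpolation; an 11-point mode is available), and the F1 at
#' the operating point (list prefix) that maximizes it.
#'
#' @param flags logical TP/FP flags in descending-score order (e.g. the `tp`
#'   column of [match_detections()]).
#' @param n_gt number of ground-truth boxes.
#' @param interpolation `"all-point"` (default) or `"11-point"`.
#' @return an `eval_report`: counts at the best-F1 operating point
#'   (`tp`, `fp`, `fn`, `precision`, `recall`, `f1`), the full `pr_curve`
#'   tibble, and `ap50`.
#' @export
pr_curve_and_ap <- function(flags, n_gt,
                            interpolation = c("all-point", "11-point")) {
  interpolation <- match.arg(interpolation)
  validate_that(n_gt >= 0, "n_gt must be nonnegative")
  flags <- as.logical(flags)
  n <- length(flags)
  if (n_gt == 0) {
    if (n > 0) rlang::warn("recall undefined with no ground truth; AP = 0 by convention")
    return(new_eval_report(tp = 0, fp = n, fn = 0, precision = 0, recall = NA_real_,
                           f1 = 0, ap50 = 0,
                           pr_curve = tibble::tibble(recall = numeric(),
                                                     precision = numeric())))
  }
  if (n == 0) {
    return(new_eval_report(tp = 0, fp = 0, fn = n_gt, precision = 0, recall = 0,
                           f1 = 0, ap50 = 0,
                           pr_curve = tibble::tibble(recall = numeric(),
                                                     precision = numeric())))
  }
  ctp <- cumsum(flags)
  cfp <- cumsum(!flags)
  prec <- ctp / (ctp + cfp)
  rec <- ctp / n_gt
  env <- rev(cummax(rev(prec)))   # precision envelope
  ap <- if (interpolation == "all-point") {
    sum((rec - c(0, head(rec, -1))) * env)
  } else {
    mean(vapply(seq(0, 1, 0.1), function(r) {
      ok <- rec >= r - 1e-12
      if (any(ok)) max(prec[ok]) else 0
    }, numeric(1)))
  }
  f1s <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  iopt <- which.max(f1s)
  new_eval_report(tp = ctp[iopt], fp = cfp[iopt], fn = n_gt - ctp[iopt],
                  precision = prec[iopt], recall = rec[iopt], f1 = f1s[iopt],
                  ap50 = ap,
                  pr_curve = tibble::tibble(recall = rec, precision = prec))
}

new_eval_report <- function(tp, fp, fn, precision, recall, f1, ap50, pr_curve) {
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1, ap50 = ap50, pr_curve = pr_curve),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> AP@0.5 = %.4f | best-F1 point: P = %.4f, ",
                     "R = %s, F1 = %.4f (TP %d, FP %d, FN %d)\n"),
              x$ap50, x$precision,
              if (is.na(x$recall)) "NA" else sprintf("%.4f", x$recall),
              x$f1, as.integer(x$tp), as.integer(x$fp), as.integer(x$fn)))
  invisible(x)
}

#' Evaluate per-image detections against per-image ground truth
#'
#' Pools score-ranked match flags across images into one PR curve.
#'
#' @param detections_by_image list of detections tibbles.
#' @param gt_by_image list of annotation tibbles, same length/order.
#' @param iou_threshold match threshold.
#' @param interpolation AP interpolation mode, see [pr_curve_and_ap()].
#' @return an `eval_report`.
#' @export
evaluate_detections <- function(detections_by_image, gt_by_image,
                                iou_threshold = 0.5,
                                interpolation = "all-point") {
  validate_that(length(detections_by_image) == length(gt_by_image),
                "detection and ground-truth lists must align")
  matched <- purrr::map2(detections_by_image, gt_by_image, match_detections,
                         iou_threshold = iou_threshold)
  pooled <- dplyr::bind_rows(lapply(seq_along(matched), function(i) {
    m <- matched[[i]]
    tibble::tibble(score = m$score, w = m$w, h = m$h, cx = m$cx, cy = m$cy,
                   tp = m$tp)
  }))
  pooled <- pooled[det_order(pooled), , drop = FALSE]
  n_gt <- sum(vapply(gt_by_image, nrow, numeric(1)))
  pr_curve_and_ap(pooled$tp, n_gt, interpolation)
}

#' Run a model over a labeled dataset and score it
#'
#' Inference, suppression, greedy matching and PR aggregation in one call.
#'
#' @param model a `yolo_model`.
#' @param dataset list of [labeled_image()]s at the model's input size.
#' @param config a [suppression_config()].
#' @param conf_threshold decoder confidence floor before suppression.
#' @param iou_threshold match threshold for scoring.
#' @return an `eval_report`; the per-image detections are attached as the
#'   `detections` attribute.
#' @export
evaluate_model <- function(model, dataset, config = suppression_config(),
                           conf_threshold = 0.001, iou_threshold = 0.5) {
  validate_that(length(dataset) > 0, "empty dataset")
  dets <- lapply(dataset, function(im) {
    raw <- forward_model(model, im$pixels / 255)
    det <- decode_predictions(raw, model$config$anchors, model$config$input_size,
                              model$strides, model$config$num_classes,
                              conf_threshold)
    rescreen(det, config)
  })
  gts <- lapply(dataset, function(im) im$annotations)
  rep <- evaluate_detections(dets, gts, iou_threshold)
  attr(rep, "detections") <- dets
  rep
}
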