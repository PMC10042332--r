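# Prior-box generation: K-means clustering of ground-truth (w, h) pairs
# under the 1 - IoU distance of origin-aligned rectangles, and assignment of
# the nine resulting centers to the three prediction scales.

#' Construct / normalize an anchor set
#'
#' Sorts nine (w, h) pairs by ascending area (ties broken by w, then h) and
#' partitions them into three triplets: the smallest-area triplet serves the
#' highest-resolution head (stride 8), the largest the stride-32 head.
#'
#' @param wh a 9 x 2 matrix or a tibble/data.frame with columns `w`, `h`.
#' @return an `anchor_set`: tibble with columns `w`, `h`, `scale` (1-3).
#' @export
assign_anchor_scales <- function(wh) {
  if (inherits(wh, "anchor_set")) wh <- as.matrix(wh[, c("w", "h")])
  if (is.data.frame(wh)) wh <- as.matrix(wh[, c("w", "h")])
  validate_that(nrow(wh) == 9 && ncol(wh) == 2, "an anchor set holds exactly 9 (w, h) pairs")
  validate_that(all(wh > 0), "anchor dimensions must be positive")
  ord <- order(wh[, 1] * wh[, 2], wh[, 1], wh[, 2])
  out <- tibble::tibble(w = wh[ord, 1], h = wh[ord, 2],
                        scale = rep(1:3, each = 3L))
  class(out) <- c("anchor_set", class(out))
  out
}

anchor_matrix <- function(anchors) {
  stopifnot(inherits(anchors, "anchor_set"))
  cbind(w = anchors$w, h = anchors$h, scale = anchors$scale)
}

#' The package's default prior boxes
#'
#' The nine tank-fish priors at 640 px reference resolution, rescaled to
#' the requested input size.
#'
#' @param input_size input resolution in pixels.
#' @return an `anchor_set`.
#' @export
default_anchors <- function(input_size = 640L) {
  wh <- matrix(c(12, 72, 46, 27, 16, 81, 21, 76, 44, 39, 28, 63,
                 20, 97, 41, 58, 35, 79), ncol = 2, byrow = TRUE)
  assign_anchor_scales(wh * input_size / 640)
}

# IoU of origin-aligned rectangles: n x 2 sizes against k x 2 centers
aligned_iou <- function(wh, centers) {
  mw <- outer(wh[, 1], centers[, 1], pmin)
  mh <- outer(wh[, 2], centers[, 2], pmin)
  inter <- mw * mh
  areas <- wh[, 1] * wh[, 2]
  careas <- centers[, 1] * centers[, 2]
  inter / (outer(areas, careas, `+`) - inter)
}

kmeanspp_init <- function(wh, k, dist_fn) {
  n <- nrow(wh)
  centers <- matrix(0, k, 2)
  centers[1, ] <- wh[sample.int(n, 1), ]
  if (k > 1) for (j in 2:k) {
    d <- apply(dist_fn(wh, centers[seq_len(j - 1), , drop = FALSE]), 1, min)
    w <- d^2
    pick <- if (sum(w) <= 0) sample.int(n, 1) else sample.int(n, 1, prob = w)
    centers[j, ] <- wh[pick, ]
  }
  centers
}

lloyd_iou <- function(wh, k, max_iter = 100L) {
  dist_fn <- function(x, cc) 1 - aligned_iou(x, cc)
  centers <- kmeanspp_init(wh, k, dist_fn)
  trace <- numeric(0)
  best <- list(objective = Inf, centers = centers, cluster = NULL)
  for (it in seq_len(max_iter)) {
    d <- dist_fn(wh, centers)
    cl <- max.col(-d, ties.method = "first")
    obj <- mean(d[cbind(seq_len(nrow(wh)), cl)])
    # mean-update Lloyd under the 1 - IoU objective: stop (keeping the
    # previous state) the moment the objective fails to decrease, so the
    # recorded trace is non-increasing by construction
    if (obj > best$objective - 1e-12) break
    trace <- c(trace, obj)
    best <- list(objective = obj, centers = centers, cluster = cl)
    newc <- centers
    for (j in seq_len(k)) {
      m <- cl == j
      if (any(m)) newc[j, ] <- colMeans(wh[m, , drop = FALSE])
    }
    if (max(abs(newc - centers)) < 1e-10) break
    centers <- newc
  }
  c(best, list(trace = trace))
}

#' Cluster ground-truth box sizes into prior boxes
#'
#' Lloyd-style K-means on (w, h) pairs under the distance
#' `d(box, center) = 1 - IoU` of origin-aligned rectangles (the convention
#' natural to prior boxes: two sizes are close when a box of one size
#' overlaps a concentric box of the other well).  `restarts` independent
#' k-means++ initializations are run and the solution with the lowest mean
#' distance is kept.
#'
#' @param boxes a tibble/data.frame with columns `w`, `h` (pixels at the
#'   reference input resolution), or an annotation tibble.
#' @param k number of clusters (9 for the three-scale detector).
#' @param seed RNG seed.
#' @param restarts number of independent restarts.
#' @param distance `"iou"` (default) or `"euclidean"` (delegates to
#'   [stats::kmeans()] on the raw (w, h) plane, for comparison).
#' @return an `anchor_set` (see [assign_anchor_scales()]); attributes
#'   `objective` (mean distance of the winning run) and `trace` (its
#'   per-iteration objective sequence, non-increasing).
#' @export
kmeans_anchors <- function(boxes, k = 9L, seed = 0L, restarts = 10L,
                           distance = c("iou", "euclidean")) {
  distance <- match.arg(distance)
  wh <- as.matrix(as.data.frame(boxes)[, c("w", "h")])
  validate_that(all(wh > 0), "box dimensions must be positive")
  validate_that(nrow(wh) >= k, sprintf("need at least k = %d boxes, got %d", k, nrow(wh)))
  if (distance == "euclidean") {
    km <- withr::with_seed(as.integer(seed),
                           stats::kmeans(wh, centers = k, nstart = restarts))
    out <- anchors_out(km$centers, k)
    attr(out, "objective") <- km$tot.withinss / nrow(wh)
    return(out)
  }
  best <- NULL
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(restarts)) {
      run <- lloyd_iou(wh, k)
      if (is.null(best) || run$objective < best$objective) best <- run
    }
  })
  if (best$objective < 1e-12 && nrow(unique(wh)) < k) {
    rlang::warn("degenerate clustering: fewer distinct box sizes than clusters")
  }
  out <- anchors_out(best$centers, k)
  attr(out, "objective") <- best$objective
  attr(out, "trace") <- best$trace
  out
}

# nine centers become a scale-partitioned anchor_set; other k stay a plain
# area-sorted tibble of centers
anchors_out <- function(centers, k) {
  if (k == 9L) return(assign_anchor_scales(centers))
  ord <- order(centers[, 1] * centers[, 2], centers[, 1], centers[, 2])
  tibble::tibble(w = centers[ord, 1], h = centers[ord, 2])
}
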