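# Training-time augmentation: Mosaic-8 composition with photometric jitter.
#
# Mosaic-8 extends the classic four-image mosaic to eight: each labeled
# image is independently scaled and cropped, then composited onto a single
# canvas in a 4 x 2 cell layout with jittered cell boundaries; ground-truth
# boxes ride along under the same affine placement and are clipped to their
# cell, with degenerate slivers dropped.

#' Augmentation configuration
#'
#' @param mosaic8_prob probability that a training sample is a Mosaic-8
#'   composite rather than a raw image.
#' @param brightness_range multiplicative brightness interval.
#' @param noise_sigma_range additive Gaussian noise std interval.
#' @param min_box_area_px drop a clipped box below this area.
#' @param min_box_frac drop a clipped box below this fraction of its
#'   original area.
#' @param boundary_jitter cell-boundary jitter as a fraction of cell size.
#' @param scale_jitter extra random up-scaling beyond cell coverage (0 means
#'   each image is scaled to exactly cover its cell).
#' @param canvas_size output canvas in pixels.
#' @param seed integer seed.
#' @return an `augment_config` list.
#' @export
augment_config <- function(mosaic8_prob = 0.5,
                           brightness_range = c(0.8, 1.2),
                           noise_sigma_range = c(0, 8),
                           min_box_area_px = 8,
                           min_box_frac = 0.2,
                           boundary_jitter = 0.2,
                           scale_jitter = 0.5,
                           canvas_size = 640L,
                           seed = 0L) {
  validate_that(mosaic8_prob >= 0 && mosaic8_prob <= 1,
                "mosaic8_prob must lie in [0, 1]")
  validate_that(min_box_area_px >= 0 && min_box_frac >= 0,
                "box-drop thresholds must be nonnegative")
  structure(list(mosaic8_prob = mosaic8_prob, brightness_range = brightness_range,
                 noise_sigma_range = noise_sigma_range,
                 min_box_area_px = min_box_area_px, min_box_frac = min_box_frac,
                 boundary_jitter = boundary_jitter, scale_jitter = scale_jitter,
                 canvas_size = as.integer(canvas_size), seed = as.integer(seed)),
            class = "augment_config")
}

#' Multiplicative brightness adjustment
#'
#' @param image `(H, W, 3)` array in `[0, 255]`.
#' @param factor positive multiplier; values clip to `[0, 255]`.
#' @export
adjust_brightness <- function(image, factor) {
  validate_that(factor > 0, "brightness factor must be positive")
  pmin(pmax(image * factor, 0), 255)
}

#' Additive Gaussian pixel noise
#'
#' @param image `(H, W, 3)` array in `[0, 255]`.
#' @param sigma noise standard deviation (`>= 0`).
#' @param seed integer seed; the same seed reproduces the same noise field.
#' @export
add_gaussian_noise <- function(image, sigma, seed = 0L) {
  validate_that(sigma >= 0, "sigma must be nonnegative")
  if (sigma == 0) return(image)
  noise <- withr::with_seed(as.integer(seed),
                            array(rnorm(length(image), 0, sigma), dim = dim(image)))
  pmin(pmax(image + noise, 0), 255)
}

# nearest-neighbour resize of an (H, W, 3) array
resize_nn <- function(px, new_h, new_w) {
  d <- dim(px)
  ri <- pmin(d[1], pmax(1L, ceiling(seq_len(new_h) * d[1] / new_h)))
  ci <- pmin(d[2], pmax(1L, ceiling(seq_len(new_w) * d[2] / new_w)))
  px[ri, ci, , drop = FALSE]
}

#' Mosaic-8 augmentation
#'
#' Composites exactly eight labeled images onto one `canvas_size` square
#' canvas in a 4 x 2 cell layout with jittered boundaries.  Each image is
#' randomly up-scaled (so it covers its cell) and randomly cropped; every
#' surviving ground-truth box is transformed by the same scale/translation
#' as its pixels, clipped to its cell, and dropped when the clipped area
#' falls below `min_box_area_px` or below `min_box_frac` of its original
#' area.  Deterministic given `config$seed`.
#'
#' @param images list of exactly 8 [labeled_image()]s.
#' @param config an [augment_config()].
#' @return a [labeled_image()] composite.
#' @export
mosaic8 <- function(images, config = augment_config()) {
  validate_that(length(images) == 8, "mosaic8 requires exactly 8 labeled images")
  stopifnot(all(vapply(images, inherits, logical(1), "labeled_image")))
  withr::with_seed(config$seed, mosaic8_impl(images, config))
}

mosaic8_impl <- function(images, cfg) {
  S <- cfg$canvas_size
  jit <- cfg$boundary_jitter
  # jittered 4 x 2 cell boundaries
  xb <- round(S * (c(1, 2, 3) / 4 + runif(3, -jit / 4, jit / 4)))
  yb <- round(S * (1 / 2 + runif(1, -jit / 2, jit / 2)))
  xs <- c(0, xb, S)
  ys <- c(0, yb, S)
  canvas <- array(0, dim = c(S, S, 3))
  ann_out <- list()
  transforms <- vector("list", 8L)
  k <- 0L
  for (row in 1:2) {
    for (col in 1:4) {
      k <- k + 1L
      im <- images[[k]]
      cw <- xs[col + 1] - xs[col]
      chh <- ys[row + 1] - ys[row]
      d <- dim(im$pixels)
      cover <- max(cw / d[2], chh / d[1])
      sc <- cover * runif(1, 1.0, 1.0 + cfg$scale_jitter)
      nh <- max(chh, round(d[1] * sc)); nw <- max(cw, round(d[2] * sc))
      scaled <- resize_nn(im$pixels, nh, nw)
      sx <- nw / d[2]; sy <- nh / d[1]     # realized scale factors
      ox <- sample.int(nw - cw + 1L, 1L) - 1L
      oy <- sample.int(nh - chh + 1L, 1L) - 1L
      canvas[(ys[row] + 1):(ys[row + 1]), (xs[col] + 1):(xs[col + 1]), ] <-
        scaled[(oy + 1):(oy + chh), (ox + 1):(ox + cw), , drop = FALSE]
      transforms[[k]] <- list(sx = sx, sy = sy, ox = ox, oy = oy,
                              cell = c(xs[col], ys[row], xs[col + 1], ys[row + 1]))
      ann <- im$annotations
      if (nrow(ann) > 0) {
        # the same affine as the pixels: scale, subtract crop, add cell origin
        bx <- tibble::tibble(
          class = ann$class,
          cx = ann$cx * sx - ox + xs[col],
          cy = ann$cy * sy - oy + ys[row],
          w = ann$w * sx, h = ann$h * sy,
          difficult = ann$difficult)
        orig_area <- bx$w * bx$h
        xmin <- pmax(bx$cx - bx$w / 2, xs[col]); xmax <- pmin(bx$cx + bx$w / 2, xs[col + 1])
        ymin <- pmax(bx$cy - bx$h / 2, ys[row]); ymax <- pmin(bx$cy + bx$h / 2, ys[row + 1])
        wn <- pmax(xmax - xmin, 0); hn <- pmax(ymax - ymin, 0)
        keep <- wn * hn >= cfg$min_box_area_px & wn * hn >= cfg$min_box_frac * orig_area
        if (any(keep)) {
          bx <- bx[keep, , drop = FALSE]
          bx$cx <- ((xmin + xmax) / 2)[keep]; bx$w <- wn[keep]
          bx$cy <- ((ymin + ymax) / 2)[keep]; bx$h <- hn[keep]
          ann_out[[length(ann_out) + 1L]] <- bx
        }
      }
    }
  }
  ann <- if (length(ann_out)) dplyr::bind_rows(ann_out) else empty_annotations()
  # photometric jitter on the composite
  canvas <- adjust_brightness(canvas, runif(1, cfg$brightness_range[1],
                                            cfg$brightness_range[2]))
  sg <- runif(1, cfg$noise_sigma_range[1], cfg$noise_sigma_range[2])
  canvas <- add_gaussian_noise(canvas, sg, seed = sample.int(2^30, 1))
  out <- labeled_image(pixels = canvas, annotations = ann,
                       source_id = paste0("mosaic8_", cfg$seed))
  attr(out, "transforms") <- transforms
  out
}
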