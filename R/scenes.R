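# Synthetic top-view tank scenes: a circular tank disc seen from above with
# ellipse-bodied, triangle-tailed fish at controllable density, occlusion,
# brightness and noise, each with a tight bounding-box annotation.  The
# generator stands in for overhead 1080P captures of a circular
# recirculating-aquaculture tank so that the full pipeline is testable with
# no external data.

#' Scene generator configuration
#'
#' @param image_size `c(W, H)` canvas in pixels.
#' @param n_fish number of fish to place.
#' @param fish_length_range min/max body length in pixels.
#' @param aspect_range min/max body length : width ratio.
#' @param occlusion_mode `"none"` (disjoint boxes), `"parallel"` /
#'   `"cross"` (placed pairs of side-by-side / crossing fish with box IoU at
#'   least `min_pair_iou`), or `"dense"` (all fish crowded into a small
#'   region, overlaps unconstrained).
#' @param n_pairs number of occluded pairs for the pair modes (default:
#'   `floor(n_fish / 2)`).
#' @param min_pair_iou required pairwise box IoU for placed pairs.
#' @param brightness_factor min/max multiplicative brightness, applied last.
#' @param noise_sigma min/max additive Gaussian noise std, applied last.
#' @param tank_margin fraction of the half-width kept free around the tank.
#' @param seed integer seed; scenes are fully reproducible from it.
#' @return a `scene_config` list.
#' @export
scene_config <- function(image_size = c(640L, 640L),
                         n_fish = 8L,
                         fish_length_range = c(55, 100),
                         aspect_range = c(2.8, 4.2),
                         occlusion_mode = c("none", "parallel", "cross", "dense"),
                         n_pairs = NULL,
                         min_pair_iou = 0.3,
                         brightness_factor = c(1, 1),
                         noise_sigma = c(0, 0),
                         tank_margin = 0.04,
                         seed = 0L) {
  occlusion_mode <- match.arg(occlusion_mode)
  if (length(image_size) == 1) image_size <- rep(image_size, 2)
  validate_that(n_fish >= 0, "n_fish must be nonnegative")
  for (rg in list(fish_length_range, aspect_range, brightness_factor, noise_sigma)) {
    validate_that(length(rg) == 2 && rg[1] <= rg[2], "ranges must satisfy low <= high")
  }
  validate_that(min_pair_iou >= 0 && min_pair_iou < 1, "min_pair_iou must lie in [0, 1)")
  if (is.null(n_pairs)) {
    n_pairs <- if (occlusion_mode %in% c("parallel", "cross")) n_fish %/% 2L else 0L
  }
  validate_that(2 * n_pairs <= n_fish, "n_pairs cannot exceed n_fish / 2")
  structure(list(image_size = as.integer(image_size), n_fish = as.integer(n_fish),
                 fish_length_range = fish_length_range, aspect_range = aspect_range,
                 occlusion_mode = occlusion_mode, n_pairs = as.integer(n_pairs),
                 min_pair_iou = min_pair_iou, brightness_factor = brightness_factor,
                 noise_sigma = noise_sigma, tank_margin = tank_margin,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' A small-scene preset for CPU tests
#'
#' 160 x 160 canvas with proportionally scaled fish.
#'
#' @param ... overrides passed to [scene_config()].
#' @export
tiny_scene_config <- function(...) {
  args <- list(...)
  defaults <- list(image_size = c(160L, 160L), n_fish = 3L,
                   fish_length_range = c(28, 45), aspect_range = c(2.8, 4.2))
  do.call(scene_config, utils::modifyList(defaults, args))
}

# Rasterize one fish (ellipse torso + flared triangular tail) into a local
# logical mask.  Returns the mask window and the tight box in center form.
render_fish_mask <- function(x0, y0, theta, len, wid, W, H) {
  a <- 0.38 * len            # torso semi-major
  b <- wid / 2
  half <- 0.55 * len
  c0 <- max(1L, floor(x0 - half)); c1 <- min(W, ceiling(x0 + half))
  r0 <- max(1L, floor(y0 - half)); r1 <- min(H, ceiling(y0 + half))
  if (c1 < c0 || r1 < r0) return(NULL)
  xs <- (c0:c1) - 0.5
  ys <- (r0:r1) - 0.5
  px <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE) - x0
  py <- matrix(ys, nrow = length(ys), ncol = length(xs)) - y0
  u <- cos(theta) * px + sin(theta) * py      # along body axis
  v <- -sin(theta) * px + cos(theta) * py     # across body
  torso <- (u / a)^2 + (v / b)^2 <= 1
  # tail: apex inside the torso, flared base at the rear end of the body
  ax <- -0.30 * len; bx <- -0.5 * len; bw <- 0.35 * wid
  tail <- u <= ax & u >= bx & abs(v) <= bw * (ax - u) / (ax - bx)
  mask <- torso | tail
  if (!any(mask)) return(NULL)
  cols <- which(apply(mask, 2, any)); rows <- which(apply(mask, 1, any))
  xmin <- (c0 - 1) + (cols[1] - 1); xmax <- (c0 - 1) + cols[length(cols)]
  ymin <- (r0 - 1) + (rows[1] - 1); ymax <- (r0 - 1) + rows[length(rows)]
  list(mask = mask, r0 = r0, c0 = c0,
       box = tibble::tibble(cx = (xmin + xmax) / 2, cy = (ymin + ymax) / 2,
                            w = xmax - xmin, h = ymax - ymin))
}

# sample a fish whose body circle stays inside the tank
sample_fish <- function(cfg, cx0, cy0, tank_r, theta = NULL, center = NULL,
                        spread = NULL) {
  len <- runif(1, cfg$fish_length_range[1], cfg$fish_length_range[2])
  wid <- len / runif(1, cfg$aspect_range[1], cfg$aspect_range[2])
  if (is.null(theta)) theta <- runif(1, 0, 2 * pi)
  rmax <- max(tank_r - 0.55 * len, 1)
  if (is.null(center)) {
    rr <- sqrt(runif(1)) * rmax
    ph <- runif(1, 0, 2 * pi)
    x0 <- cx0 + rr * cos(ph); y0 <- cy0 + rr * sin(ph)
  } else {
    x0 <- center[1] + rnorm(1, 0, spread)
    y0 <- center[2] + rnorm(1, 0, spread)
    d <- sqrt((x0 - cx0)^2 + (y0 - cy0)^2)
    if (d > rmax) {
      x0 <- cx0 + (x0 - cx0) * rmax / d
      y0 <- cy0 + (y0 - cy0) * rmax / d
    }
  }
  list(x0 = x0, y0 = y0, theta = theta, len = len, wid = wid)
}

#' Generate one synthetic tank scene
#'
#' Renders a circular tank disc with `n_fish` fish inside it, applies the
#' configured brightness factor and additive Gaussian noise last, and
#' returns the image together with the tight bounding box of each rendered
#' fish silhouette (computed before noise).  Fully reproducible from
#' `config$seed`.
#'
#' @param config a [scene_config()].
#' @param keep_masks if `TRUE`, attach the per-fish silhouette masks as the
#'   `"masks"` attribute (used by geometry checks).
#' @return a [labeled_image()]; annotations carry class `"fish"`.
#' @export
generate_scene <- function(config = scene_config(), keep_masks = FALSE) {
  stopifnot(inherits(config, "scene_config"))
  withr::with_seed(config$seed, generate_scene_impl(config, keep_masks))
}

generate_scene_impl <- function(cfg, keep_masks) {
  W <- cfg$image_size[1]; H <- cfg$image_size[2]
  cx0 <- W / 2; cy0 <- H / 2
  tank_r <- (min(W, H) / 2) * (1 - cfg$tank_margin)
  attempts_budget <- 1000L
  fishes <- list()
  boxes <- assign_boxes <- NULL
  add_fish <- function(f) {
    rf <- render_fish_mask(f$x0, f$y0, f$theta, f$len, f$wid, W, H)
    if (is.null(rf)) return(NULL)
    rf
  }
  placed <- list()      # list of list(f, rf)
  boxes_df <- empty_annotations()[, c("cx", "cy", "w", "h")]
  place_with <- function(accept) {
    for (att in seq_len(attempts_budget)) {
      f <- sample_fish(cfg, cx0, cy0, tank_r)
      rf <- add_fish(f)
      if (is.null(rf)) next
      if (accept(rf)) return(list(f = f, rf = rf))
    }
    NULL
  }
  no_overlap <- function(rf) {
    nrow(boxes_df) == 0 || all(iou(rf$box, boxes_df) == 0)
  }
  mild_overlap <- function(rf) {
    nrow(boxes_df) == 0 || all(iou(rf$box, boxes_df) < 0.1)
  }
  n_placed_target <- cfg$n_fish
  fail_placement <- function() {
    abort_fishdet(sprintf("could not place %d fish (achieved %d) within the attempt budget",
                          n_placed_target, length(placed)),
                  "fishdet_placement_error")
  }
  push <- function(p) {
    placed[[length(placed) + 1L]] <<- p
    boxes_df <<- dplyr::bind_rows(boxes_df, p$rf$box)
  }
  if (cfg$occlusion_mode %in% c("parallel", "cross") && cfg$n_pairs > 0) {
    for (k in seq_len(cfg$n_pairs)) {
      ok <- FALSE
      for (att in seq_len(attempts_budget)) {
        f1 <- sample_fish(cfg, cx0, cy0, tank_r)
        rf1 <- add_fish(f1)
        if (is.null(rf1) || !mild_overlap(rf1)) next
        th2 <- if (cfg$occlusion_mode == "parallel") {
          f1$theta + runif(1, -0.15, 0.15)
        } else {
          f1$theta + pi / 2 + runif(1, -0.15, 0.15)
        }
        off <- runif(1, 0.3, 0.9) * f1$wid
        dirn <- f1$theta + pi / 2
        f2 <- sample_fish(cfg, cx0, cy0, tank_r, theta = th2,
                          center = c(f1$x0 + off * cos(dirn),
                                     f1$y0 + off * sin(dirn)),
                          spread = 0.15 * f1$len)
        rf2 <- add_fish(f2)
        if (is.null(rf2)) next
        if (iou(rf1$box, rf2$box) >= cfg$min_pair_iou &&
              (nrow(boxes_df) == 0 || all(iou(rf1$box, boxes_df) < 0.1) &&
                 all(iou(rf2$box, boxes_df) < 0.1))) {
          push(list(f = f1, rf = rf1)); push(list(f = f2, rf = rf2))
          ok <- TRUE
          break
        }
      }
      if (!ok) fail_placement()
    }
  }
  n_single <- cfg$n_fish - length(placed)
  if (cfg$occlusion_mode == "dense" && n_single > 0) {
    crowd_r <- 0.35 * tank_r
    ph <- runif(1, 0, 2 * pi)
    crowd <- c(cx0 + runif(1, 0, tank_r - crowd_r) * cos(ph),
               cy0 + runif(1, 0, tank_r - crowd_r) * sin(ph))
    for (k in seq_len(n_single)) {
      got <- NULL
      for (att in seq_len(attempts_budget)) {
        f <- sample_fish(cfg, cx0, cy0, tank_r, center = crowd, spread = crowd_r / 2)
        rf <- add_fish(f)
        if (!is.null(rf)) { got <- list(f = f, rf = rf); break }
      }
      if (is.null(got)) fail_placement()
      push(got)
    }
  } else if (n_single > 0) {
    accept <- if (cfg$occlusion_mode == "none") no_overlap else mild_overlap
    for (k in seq_len(n_single)) {
      got <- place_with(accept)
      if (is.null(got)) fail_placement()
      push(got)
    }
  }
  # ---- raster ----
  bg <- c(34, 40, 46)
  tank_col <- c(68, 80, 88)
  img <- array(rep(bg, each = H * W), dim = c(H, W, 3))
  pxg <- matrix(seq_len(W) - 0.5, H, W, byrow = TRUE)
  pyg <- matrix(seq_len(H) - 0.5, H, W)
  disc <- (pxg - cx0)^2 + (pyg - cy0)^2 <= tank_r^2
  for (ch in 1:3) {
    pl <- img[, , ch]
    pl[disc] <- tank_col[ch]
    img[, , ch] <- pl
  }
  masks <- vector("list", length(placed))
  for (i in seq_along(placed)) {
    p <- placed[[i]]
    shade <- runif(1, 140, 195)
    tint <- shade * c(1, runif(1, 0.96, 1.0), runif(1, 0.88, 0.96))
    m <- p$rf$mask
    rr <- p$rf$r0:(p$rf$r0 + nrow(m) - 1L)
    cc <- p$rf$c0:(p$rf$c0 + ncol(m) - 1L)
    for (ch in 1:3) {
      win <- img[rr, cc, ch]
      win[m] <- tint[ch]
      img[rr, cc, ch] <- win
    }
    masks[[i]] <- p$rf[c("mask", "r0", "c0", "box")]
  }
  # photometrics last: brightness then noise, clipped to [0, 255]
  bf <- runif(1, cfg$brightness_factor[1], cfg$brightness_factor[2])
  img <- img * bf
  sg <- runif(1, cfg$noise_sigma[1], cfg$noise_sigma[2])
  if (sg > 0) img <- img + array(rnorm(length(img), 0, sg), dim = dim(img))
  img <- round(pmin(pmax(img, 0), 255))
  ann <- if (length(placed)) {
    dplyr::bind_rows(lapply(placed, function(p) p$rf$box))
  } else {
    empty_annotations()[, c("cx", "cy", "w", "h")]
  }
  ann <- tibble::tibble(class = rep("fish", nrow(ann)), ann, difficult = FALSE)
  im <- labeled_image(pixels = img, annotations = ann,
                      source_id = sprintf("scene_%06d", cfg$seed))
  if (keep_masks) attr(im, "masks") <- masks
  im
}

#' Generate a dataset of synthetic scenes on disk
#'
#' Writes the `images/` + `labels/` layout under per-split directories with
#' deterministic per-image seeds derived from the master seed.
#'
#' @param config a [scene_config()]; its `seed` is the master seed.
#' @param n_images total number of scenes.
#' @param out_dir output directory (created).
#' @param split named fractions summing to 1 (splits in the given order).
#' @param format `"xml"` (VOC) or `"txt"` (YOLO lines).
#' @return tibble with one row per split: `split`, `n`, `dir`.
#' @export
generate_dataset <- function(config = scene_config(), n_images, out_dir,
                             split = c(train = 0.8, val = 0.1, test = 0.1),
                             format = c("xml", "txt")) {
  format <- match.arg(format)
  validate_that(abs(sum(split) - 1) < 1e-9, "split fractions must sum to 1")
  counts <- diff(c(0, floor(cumsum(split) * n_images)))
  names(counts) <- names(split)
  splits <- rep(names(split), counts)
  idx <- tibble::tibble(split = names(counts), n = as.integer(counts),
                        dir = file.path(out_dir, names(counts)))
  for (d in idx$dir) {
    ok <- dir.create(file.path(d, "images"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(d, "labels"), recursive = TRUE, showWarnings = FALSE)
  }
  validate_that(dir.exists(out_dir), paste0("cannot create output directory: ", out_dir),
                class = "fishdet_io_error")
  for (i in seq_len(n_images)) {
    cfg_i <- config
    cfg_i$seed <- child_seed(config$seed, i)
    im <- generate_scene(cfg_i)
    im$source_id <- sprintf("scene_%04d", i)
    sdir <- file.path(out_dir, splits[i])
    write_image(im$pixels, file.path(sdir, "images", paste0(im$source_id, ".png")))
    if (format == "xml") {
      write_voc_xml(im, file.path(sdir, "labels", paste0(im$source_id, ".xml")))
    } else {
      write_yolo_txt(im, file.path(sdir, "labels", paste0(im$source_id, ".txt")))
    }
  }
  idx
}

#' Load every labeled image of a dataset split
#'
#' @param dir a split directory in the `images/` + `labels/` layout.
#' @param classes class vocabulary.
#' @return list of [labeled_image()]s.
#' @export
load_dataset <- function(dir, classes = "fish") {
  ix <- index_dataset(dir)
  purrr::map2(ix$image, ix$label, load_labeled_image, classes = classes)
}
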