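# Orchestration: run configuration, synthetic-dataset creation, anchor
# generation, training, detection and evaluation as single calls (the same
# entry points the command-line wrapper exposes).

#' Run configuration
#'
#' Bundles every stage's configuration plus the optimization
#' hyperparameters.  The default profile is the CPU-friendly synthetic
#' quickstart (batch 4, 20 epochs, lr 0.005, cosine annealing); the
#' `"reference"` profile is the full-scale recipe (Adam, lr 0.01, batch 32,
#' 200 epochs, 640 px) intended for accelerator-scale data.
#'
#' @param profile `"tiny"` or `"reference"`.
#' @param scene a [scene_config()] for synthetic data.
#' @param n_images number of synthetic images to generate when no dataset
#'   directory is given.
#' @param data_dir existing dataset root (with train/ val/ test/ splits), or
#'   `NULL` to generate synthetic data into `out_dir/data`.
#' @param model a [model_config()] (tiny profile default:
#'   [tiny_model_config()] with CA enabled).
#' @param augment an [augment_config()] or `NULL` to disable augmentation.
#' @param loss a [loss_config()].
#' @param suppression a [suppression_config()].
#' @param learning_rate,batch_size,epochs optimization hyperparameters
#'   (profile defaults when `NULL`).
#' @param optimizer only `"adam"` is implemented.
#' @param scheduler only `"cosine"` is implemented.
#' @param auto_anchors re-cluster prior boxes from the training labels.
#' @param seed master seed.
#' @param out_dir run output directory.
#' @return a `run_config` list.
#' @export
run_config <- function(profile = c("tiny", "reference"),
                       scene = NULL, n_images = 64L, data_dir = NULL,
                       model = NULL, augment = NULL, loss = loss_config(),
                       suppression = suppression_config(),
                       learning_rate = NULL, batch_size = NULL, epochs = NULL,
                       optimizer = "adam", scheduler = "cosine",
                       auto_anchors = TRUE, seed = 0L, out_dir = "runs/exp") {
  profile <- match.arg(profile)
  if (profile == "tiny") {
    if (is.null(model)) model <- tiny_model_config()
    if (is.null(scene)) scene <- tiny_scene_config(seed = seed)
    learning_rate <- learning_rate %||% 0.005
    batch_size <- batch_size %||% 4L
    epochs <- epochs %||% 20L
  } else {
    if (is.null(model)) model <- model_config(ca_sites = c("backbone_c3", "neck"))
    if (is.null(scene)) scene <- scene_config(seed = seed)
    learning_rate <- learning_rate %||% 0.01
    batch_size <- batch_size %||% 32L
    epochs <- epochs %||% 200L
  }
  validate_that(epochs >= 1 && batch_size >= 1 && learning_rate > 0,
                "epochs >= 1, batch_size >= 1, learning_rate > 0 required")
  validate_that(identical(optimizer, "adam"), "only the adam optimizer is implemented")
  validate_that(identical(scheduler, "cosine"), "only cosine annealing is implemented")
  structure(list(profile = profile, scene = scene, n_images = as.integer(n_images),
                 data_dir = data_dir, model = model, augment = augment,
                 loss = loss, suppression = suppression,
                 learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), optimizer = optimizer,
                 scheduler = scheduler, auto_anchors = auto_anchors,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Create a synthetic dataset (command entry point)
#'
#' @param out_dir output root.
#' @param n_images number of scenes.
#' @param config a [scene_config()].
#' @param split named split fractions.
#' @param format annotation dialect, `"xml"` or `"txt"`.
#' @return the split index tibble from [generate_dataset()].
#' @export
make_synthetic <- function(out_dir, n_images = 64L, config = scene_config(),
                           split = c(train = 0.8, val = 0.1, test = 0.1),
                           format = "xml") {
  generate_dataset(config, n_images, out_dir, split, format)
}

# every ground-truth (w, h) of a split, rescaled to the reference resolution
collect_box_sizes <- function(dir, input_size, classes = "fish") {
  ix <- index_dataset(dir)
  rows <- lapply(seq_len(nrow(ix)), function(i) {
    d <- dim(read_image(ix$image[i]))
    li <- read_annotations(ix$label[i], image_size = c(d[2], d[1]), classes = classes)
    ann <- li$annotations
    tibble::tibble(w = ann$w * input_size / d[2], h = ann$h * input_size / d[1])
  })
  dplyr::bind_rows(rows)
}

#' Cluster prior boxes from a dataset (command entry point)
#'
#' Runs IoU-distance K-means over every training box, rescaled to the
#' reference input resolution, and returns the nine scale-partitioned
#' priors.
#'
#' @param train_dir training split directory.
#' @param k number of clusters.
#' @param input_size reference resolution the anchors are expressed at.
#' @param seed,restarts clustering controls, see [kmeans_anchors()].
#' @return an `anchor_set`.
#' @export
make_anchors <- function(train_dir, k = 9L, input_size = 640L, seed = 0L,
                         restarts = 10L) {
  wh <- collect_box_sizes(train_dir, input_size)
  validate_that(nrow(wh) >= k,
                sprintf("dataset has %d boxes; need at least %d", nrow(wh), k))
  kmeans_anchors(wh, k = k, seed = seed, restarts = restarts)
}

#' Train from a run configuration (command entry point)
#'
#' Generates (or loads) the dataset, optionally re-clusters anchors from the
#' training labels, builds the model and trains it.  Writes into
#' `config$out_dir`: `config.yaml` (snapshot), `checkpoint.rds` (lowest
#' validation loss) and `log.csv` (per-epoch losses).
#'
#' @param config a [run_config()].
#' @param overwrite allow reuse of an existing run directory.
#' @param verbose per-epoch progress.
#' @return a `training_run` (invisibly), with `checkpoint` and `data_dir`
#'   attributes.
#' @export
train_run <- function(config = run_config(), overwrite = FALSE, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  od <- config$out_dir
  if (dir.exists(od) && length(list.files(od)) > 0 && !overwrite) {
    abort_fishdet(paste0("run directory exists: ", od,
                         " (use overwrite = TRUE to reuse it)"), "fishdet_io_error")
  }
  dir.create(od, recursive = TRUE, showWarnings = FALSE)
  data_dir <- config$data_dir
  if (is.null(data_dir)) {
    data_dir <- file.path(od, "data")
    if (!dir.exists(file.path(data_dir, "train"))) {
      sc <- config$scene
      sc$seed <- config$seed
      make_synthetic(data_dir, config$n_images, sc)
    }
  }
  train_ims <- load_dataset(file.path(data_dir, "train"))
  val_dir <- file.path(data_dir, "val")
  val_ims <- if (dir.exists(file.path(val_dir, "images")) &&
                   nrow(index_dataset(val_dir)) > 0) load_dataset(val_dir)
  validate_that(length(train_ims) > 0, "empty training split")
  mcfg <- config$model
  if (isTRUE(config$auto_anchors)) {
    anc <- make_anchors(file.path(data_dir, "train"),
                        input_size = mcfg$input_size, seed = config$seed)
    mcfg$anchors <- anc
  }
  model <- build_model(mcfg, seed = config$seed)
  run <- train_detector(model, train_ims, val_ims,
                        epochs = config$epochs, batch_size = config$batch_size,
                        lr = config$learning_rate, loss_cfg = config$loss,
                        aug = config$augment, seed = config$seed,
                        verbose = verbose)
  ckpt <- file.path(od, "checkpoint.rds")
  save_checkpoint(run$model, ckpt, extra = list(best_epoch = run$best_epoch))
  utils::write.csv(run$log, file.path(od, "log.csv"), row.names = FALSE)
  yaml::write_yaml(config_snapshot(config, mcfg), file.path(od, "config.yaml"))
  attr(run, "checkpoint") <- ckpt
  attr(run, "data_dir") <- data_dir
  invisible(run)
}

config_snapshot <- function(config, mcfg) {
  sn <- rapply(unclass(config), function(x) x, how = "replace")
  sn$model <- unclass(mcfg)
  sn$model$anchors <- lapply(seq_len(nrow(mcfg$anchors)), function(i) {
    c(round(mcfg$anchors$w[i], 2), round(mcfg$anchors$h[i], 2))
  })
  sn$scene <- unclass(sn$scene)
  for (f in c("loss", "suppression", "augment")) {
    if (!is.null(sn[[f]])) sn[[f]] <- unclass(sn[[f]])
  }
  sn
}

#' Detect fish in images (command entry point)
#'
#' @param checkpoint checkpoint path or a `yolo_model`.
#' @param images character vector of image paths, or a directory.
#' @param config a [suppression_config()].
#' @param conf_threshold decoder confidence floor.
#' @param annotate_dir if given, copies of the images with detection boxes
#'   burned in are written there.
#' @return tibble of detections (`image`, `class_index`, `score`, `cx, cy,
#'   w, h`) with per-image fish counts in the `counts` attribute.
#' @export
detect_images <- function(checkpoint, images, config = suppression_config(),
                          conf_threshold = 0.25, annotate_dir = NULL) {
  model <- if (inherits(checkpoint, "yolo_model")) checkpoint else
    load_checkpoint(checkpoint)
  if (length(images) == 1 && dir.exists(images)) {
    images <- list.files(images, pattern = "\\.png$", full.names = TRUE)
  }
  validate_that(length(images) > 0, "no input images")
  sz <- model$config$input_size
  out <- vector("list", length(images))
  counts <- integer(length(images))
  for (i in seq_along(images)) {
    px <- read_image(images[i])
    d <- dim(px)
    validate_that(d[1] == sz && d[2] == sz,
                  sprintf("%s is %dx%d; the checkpoint expects %dx%d",
                          images[i], d[2], d[1], sz, sz))
    raw <- forward_model(model, px / 255)
    det <- decode_predictions(raw, model$config$anchors, sz, model$strides,
                              model$config$num_classes, conf_threshold)
    det <- rescreen(det, config)
    counts[i] <- count_fish(det, score_min = conf_threshold)
    if (!is.null(annotate_dir)) {
      dir.create(annotate_dir, recursive = TRUE, showWarnings = FALSE)
      write_image(draw_boxes(px, det),
                  file.path(annotate_dir, basename(images[i])))
    }
    out[[i]] <- if (nrow(det)) {
      tibble::tibble(image = basename(images[i]), det)
    }
  }
  res <- dplyr::bind_rows(out)
  attr(res, "counts") <- setNames(counts, basename(images))
  res
}

# burn rectangle outlines into a pixel array
draw_boxes <- function(px, det, color = c(255, 80, 40), thickness = 2L) {
  d <- dim(px)
  for (i in seq_len(nrow(det))) {
    x1 <- max(1L, round(det$cx[i] - det$w[i] / 2)); x2 <- min(d[2], round(det$cx[i] + det$w[i] / 2))
    y1 <- max(1L, round(det$cy[i] - det$h[i] / 2)); y2 <- min(d[1], round(det$cy[i] + det$h[i] / 2))
    for (t in 0:(thickness - 1L)) {
      yy <- unique(pmin(pmax(c(y1 + t, y2 - t), 1L), d[1]))
      xx <- unique(pmin(pmax(c(x1 + t, x2 - t), 1L), d[2]))
      for (ch in 1:3) {
        px[yy, x1:x2, ch] <- color[ch]
        px[y1:y2, xx, ch] <- color[ch]
      }
    }
  }
  px
}

#' Evaluate a checkpoint on a labeled dataset split (command entry point)
#'
#' @param checkpoint checkpoint path or `yolo_model`.
#' @param dataset_dir split directory (`images/` + `labels/`).
#' @param config a [suppression_config()].
#' @param report_dir if given, writes `report.json`, `pr_curve.csv` and
#'   `detections.csv` there.
#' @param conf_threshold decoder confidence floor before suppression.
#' @return an `eval_report`.
#' @export
evaluate_checkpoint <- function(checkpoint, dataset_dir,
                                config = suppression_config(),
                                report_dir = NULL, conf_threshold = 0.001) {
  model <- if (inherits(checkpoint, "yolo_model")) checkpoint else
    load_checkpoint(checkpoint)
  ims <- load_dataset(dataset_dir)
  rep <- evaluate_model(model, ims, config, conf_threshold)
  if (!is.null(report_dir)) {
    dir.create(report_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(glance.eval_report(rep),
                         file.path(report_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(rep$pr_curve, file.path(report_dir, "pr_curve.csv"),
                     row.names = FALSE)
    dets <- attr(rep, "detections")
    flat <- dplyr::bind_rows(lapply(seq_along(dets), function(i) {
      if (nrow(dets[[i]])) tibble::tibble(image = i, dets[[i]])
    }))
    utils::write.csv(flat, file.path(report_dir, "detections.csv"),
                     row.names = FALSE)
  }
  rep
}
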