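# Training: Adam with single-cycle cosine learning-rate annealing, batch
# gradient accumulation on the autodiff tape, validation-loss checkpoint
# selection and CSV-compatible logging.

adam_init <- function(par) {
  list(m = lapply(par, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(par, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

# rescale gradients so their global L2 norm is at most `max_norm`
clip_gradients <- function(grads, max_norm) {
  gn <- sqrt(sum(vapply(grads, function(g) if (is.null(g)) 0 else sum(g * g),
                        numeric(1))))
  if (is.finite(gn) && gn > max_norm) {
    grads <- lapply(grads, function(g) if (is.null(g)) g else g * (max_norm / gn))
  }
  grads
}

adam_step <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(par)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    par[[nm]] <- par[[nm]] - lr * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(par = par, state = state)
}

# single-cycle cosine decay from lr0 to lr0/100
cosine_lr <- function(lr0, epoch, total_epochs) {
  lr_min <- lr0 / 100
  lr_min + 0.5 * (lr0 - lr_min) * (1 + cos(pi * (epoch - 1) / max(total_epochs - 1, 1)))
}

# loss (components) of one batch on a tape; returns nodes
batch_loss_nodes <- function(tape, model, P, ims, targets_list, cfg) {
  terms <- vector("list", length(ims))
  comp <- list(l_bbox = 0, l_cfd = 0, l_cls = 0)
  for (i in seq_along(ims)) {
    heads <- forward_model(model, ims[[i]]$pixels / 255, tape = tape, P = P)
    ls <- detection_loss_nodes(tape, heads, targets_list[[i]],
                               model$config$input_size, model$strides,
                               model$config$num_classes, cfg)
    terms[[i]] <- ls$total
    comp$l_bbox <- comp$l_bbox + vv(ls$l_bbox)
    comp$l_cfd <- comp$l_cfd + vv(ls$l_cfd)
    comp$l_cls <- comp$l_cls + vv(ls$l_cls)
  }
  total <- ag_affine(tape, ag_addn(tape, terms), 1 / length(ims))
  list(total = total, comp = lapply(comp, function(x) x / length(ims)))
}

precompute_targets <- function(model, ims, cfg, classes) {
  lapply(ims, function(im) {
    suppressWarnings(
      assign_targets(im$annotations, model$config$anchors,
                     model$config$input_size, model$strides,
                     cfg$ratio_threshold, classes))
  })
}

#' Train the detector
#'
#' Mini-batch training with Adam and single-cycle cosine annealing of the
#' learning rate down to 1/100 of its initial value.  Each epoch logs the
#' mean training loss, its components, and the composite loss on the
#' validation images; the parameter state with the lowest validation loss
#' is the one returned.
#'
#' @param model a `yolo_model` (its weights are the starting point).
#' @param train_ims list of [labeled_image()]s at the model input size.
#' @param val_ims validation list (may be `NULL`: the final state is kept).
#' @param epochs,batch_size,lr optimization hyperparameters.
#' @param loss_cfg a [loss_config()].
#' @param aug an [augment_config()] or `NULL`; with `mosaic8_prob > 0`
#'   training samples are Mosaic-8 composites with that probability.
#' @param clip_norm global gradient-norm ceiling (training without
#'   normalization layers needs it; see the methods vignette).
#' @param seed integer seed controlling shuffling and augmentation.
#' @param classes class vocabulary.
#' @param verbose print one line per epoch.
#' @return a `training_run`: list with elements `model` (best checkpoint),
#'   `log` (tibble: epoch, train_loss, val_loss, l_bbox, l_cfd, l_cls, lr)
#'   and `best_epoch`.
#' @export
train_detector <- function(model, train_ims, val_ims = NULL, epochs = 20L,
                           batch_size = 4L, lr = 0.005,
                           loss_cfg = loss_config(), aug = NULL,
                           clip_norm = 5, seed = 0L, classes = "fish",
                           verbose = FALSE) {
  validate_that(length(train_ims) > 0, "empty training split")
  validate_that(epochs >= 1 && batch_size >= 1 && lr > 0,
                "epochs >= 1, batch_size >= 1 and lr > 0 required")
  state <- adam_init(model$par)
  n <- length(train_ims)
  log_rows <- vector("list", epochs)
  best <- list(val = Inf, par = model$par, epoch = 0L)
  val_targets <- if (!is.null(val_ims)) {
    precompute_targets(model, val_ims, loss_cfg, classes)
  }
  raw_targets <- precompute_targets(model, train_ims, loss_cfg, classes)
  withr::with_seed(as.integer(seed), {
    for (ep in seq_len(epochs)) {
      lr_ep <- cosine_lr(lr, ep, epochs)
      ord <- sample.int(n)
      ep_loss <- 0; ep_comp <- c(l_bbox = 0, l_cfd = 0, l_cls = 0)
      nb <- 0L
      for (start in seq(1, n, by = batch_size)) {
        sel <- ord[start:min(start + batch_size - 1, n)]
        ims <- train_ims[sel]
        tgs <- raw_targets[sel]
        if (!is.null(aug) && aug$mosaic8_prob > 0) {
          for (j in seq_along(ims)) {
            if (runif(1) < aug$mosaic8_prob) {
              pick <- sample.int(n, 8, replace = n < 8)
              acfg <- aug
              acfg$canvas_size <- model$config$input_size
              acfg$seed <- sample.int(2^30, 1)
              mim <- mosaic8(train_ims[pick], acfg)
              ims[[j]] <- mim
              tgs[[j]] <- precompute_targets(model, list(mim), loss_cfg, classes)[[1]]
            }
          }
        }
        tape <- ag_tape()
        P <- lapply(model$par, function(p) ag_leaf(tape, p))
        bl <- batch_loss_nodes(tape, model, P, ims, tgs, loss_cfg)
        lv <- vv(bl$total)
        if (!is.finite(lv)) {
          abort_fishdet(sprintf("NaN/Inf loss at epoch %d (batch starting %d)",
                                ep, start), "fishdet_train_error")
        }
        ag_backward(tape, bl$total)
        grads <- clip_gradients(lapply(P, function(nd) nd$grad), clip_norm)
        upd <- adam_step(model$par, grads, state, lr_ep)
        model$par <- upd$par
        state <- upd$state
        ep_loss <- ep_loss + lv
        ep_comp <- ep_comp + unlist(bl$comp)
        nb <- nb + 1L
      }
      ep_loss <- ep_loss / nb
      ep_comp <- ep_comp / nb
      val_loss <- NA_real_
      if (!is.null(val_ims)) {
        vls <- vapply(seq_along(val_ims), function(i) {
          heads <- forward_model(model, val_ims[[i]]$pixels / 255)
          vv(detection_loss_nodes(NULL, heads, val_targets[[i]],
                                  model$config$input_size, model$strides,
                                  model$config$num_classes, loss_cfg)$total)
        }, numeric(1))
        val_loss <- mean(vls)
        if (val_loss < best$val) {
          best <- list(val = val_loss, par = model$par, epoch = ep)
        }
      }
      log_rows[[ep]] <- tibble::tibble(
        epoch = ep, train_loss = ep_loss, val_loss = val_loss,
        l_bbox = ep_comp[["l_bbox"]], l_cfd = ep_comp[["l_cfd"]],
        l_cls = ep_comp[["l_cls"]], lr = lr_ep)
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f  val %s  lr %.5f", ep, ep_loss,
                        ifelse(is.na(val_loss), "-", sprintf("%.4f", val_loss)),
                        lr_ep))
      }
    }
  })
  if (is.null(val_ims)) best <- list(val = NA_real_, par = model$par, epoch = epochs)
  best_model <- model
  best_model$par <- best$par
  structure(list(model = best_model, log = dplyr::bind_rows(log_rows),
                 best_epoch = best$epoch),
            class = "training_run")
}

#' @export
print.training_run <- function(x, ...) {
  lg <- x$log
  cat(sprintf("<training_run> %d epoch(s); best epoch %d; final train loss %.4f\n",
              nrow(lg), x$best_epoch, lg$train_loss[nrow(lg)]))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the model configuration (including anchors), so
#' loading rebuilds the full network structure and restores the weights.
#'
#' @param model a `yolo_model`.
#' @param path checkpoint file path (RDS).
#' @param extra optional named list stored alongside.
#' @export
save_checkpoint <- function(model, path, extra = list()) {
  saveRDS(list(par = model$par, config = unclass(model$config),
               anchors_wh = as.matrix(model$config$anchors[, c("w", "h")]),
               extra = extra), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  validate_that(file.exists(path), paste0("checkpoint not found: ", path),
                class = "fishdet_io_error")
  ck <- readRDS(path)
  cfg <- do.call(model_config, c(
    ck$config[c("num_classes", "depth_multiple", "width_multiple", "input_size",
                "ca_reduction", "ca_sites")],
    list(anchors = assign_anchor_scales(ck$anchors_wh))))
  model <- build_model(cfg)
  validate_that(identical(sort(names(model$par)), sort(names(ck$par))),
                "checkpoint does not match the configured architecture")
  model$par <- ck$par
  model
}
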