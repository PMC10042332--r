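# broom-style tidiers and ggplot2 autoplot methods for the package's
# result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an evaluation report into its PR curve
#'
#' @param x an `eval_report`.
#' @param ... unused.
#' @return tibble with columns `recall`, `precision`.
#' @export
tidy.eval_report <- function(x, ...) x$pr_curve

#' One-row summary of an evaluation report
#'
#' @inheritParams tidy.eval_report
#' @return one-row tibble: `ap50`, `precision`, `recall`, `f1`, `tp`, `fp`,
#'   `fn` (operating point = best F1).
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(ap50 = x$ap50, precision = x$precision, recall = x$recall,
                 f1 = x$f1, tp = x$tp, fp = x$fp, fn = x$fn)
}

#' Tidy a training run into its per-epoch log
#'
#' @param x a `training_run`.
#' @param ... unused.
#' @export
tidy.training_run <- function(x, ...) x$log

#' One-row summary of a training run
#'
#' @inheritParams tidy.training_run
#' @export
glance.training_run <- function(x, ...) {
  lg <- x$log
  tibble::tibble(epochs = nrow(lg), best_epoch = x$best_epoch,
                 final_train_loss = lg$train_loss[nrow(lg)],
                 best_val_loss = if (all(is.na(lg$val_loss))) NA_real_ else
                   min(lg$val_loss, na.rm = TRUE))
}

#' PR curve plot of an evaluation report
#'
#' @param object an `eval_report`.
#' @param ... unused.
#' @export
autoplot.eval_report <- function(object, ...) {
  ggplot2::ggplot(object$pr_curve, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh", color = "steelblue") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision",
                  title = sprintf("AP@0.5 = %.4f", object$ap50)) +
    ggplot2::theme_minimal()
}

#' Loss-curve plot of a training run
#'
#' @param object a `training_run`.
#' @param ... unused.
#' @export
autoplot.training_run <- function(object, ...) {
  lg <- tidyr::pivot_longer(object$log[, c("epoch", "train_loss", "val_loss")],
                            -"epoch", names_to = "split", values_to = "loss")
  lg <- lg[!is.na(lg$loss), , drop = FALSE]
  ggplot2::ggplot(lg, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   color = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Composite loss", color = NULL) +
    ggplot2::theme_minimal()
}

#' Scene plot with annotation boxes
#'
#' @param object a `labeled_image`.
#' @param detections optional detections tibble drawn in a second color.
#' @param ... unused.
#' @export
autoplot.labeled_image <- function(object, detections = NULL, ...) {
  stopifnot(!is.null(object$pixels))
  H <- object$height; W <- object$width
  rast <- grDevices::rgb(object$pixels[, , 1] / 255, object$pixels[, , 2] / 255,
                         object$pixels[, , 3] / 255)
  dim(rast) <- c(H, W)
  ann <- object$annotations
  p <- ggplot2::ggplot() +
    ggplot2::annotation_raster(rast, xmin = 0, xmax = W, ymin = -H, ymax = 0) +
    ggplot2::coord_fixed(xlim = c(0, W), ylim = c(-H, 0), expand = FALSE) +
    ggplot2::theme_void()
  if (nrow(ann) > 0) {
    p <- p + ggplot2::geom_rect(
      data = ann,
      ggplot2::aes(xmin = .data$cx - .data$w / 2, xmax = .data$cx + .data$w / 2,
                   ymin = -(.data$cy + .data$h / 2), ymax = -(.data$cy - .data$h / 2)),
      fill = NA, color = "yellow", linewidth = 0.4)
  }
  if (!is.null(detections) && nrow(detections) > 0) {
    p <- p + ggplot2::geom_rect(
      data = detections,
      ggplot2::aes(xmin = .data$cx - .data$w / 2, xmax = .data$cx + .data$w / 2,
                   ymin = -(.data$cy + .data$h / 2), ymax = -(.data$cy - .data$h / 2)),
      fill = NA, color = "red", linewidth = 0.4)
  }
  p
}

#' Anchor scatter plot
#'
#' @param object an `anchor_set`.
#' @param ... unused.
#' @export
autoplot.anchor_set <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$scale <- factor(df$scale, labels = c("P3 (stride 8)", "P4 (stride 16)",
                                          "P5 (stride 32)"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$w, y = .data$h, color = .data$scale)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = "Anchor width (px)", y = "Anchor height (px)", color = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
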