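# Shared fixture builders.  Scenes are generated in code at test time;
# nothing is read from disk except files the tests themselves write.

tiny_scenes <- local({
  cache <- new.env(parent = emptyenv())
  function(master_seed, idx, ...) {
    key <- paste0(master_seed, "_", paste(idx, collapse = ","),
                  "_", paste(deparse(list(...)), collapse = ""))
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    base <- tiny_scene_config(...)
    out <- lapply(idx, function(i) {
      cfg <- base
      cfg$seed <- fishdet:::child_seed(master_seed, i)
      generate_scene(cfg)
    })
    cache[[key]] <- out
    out
  }
})

random_annotations <- function(n, W = 200, H = 200, seed = 1) {
  withr::with_seed(seed, {
    w <- runif(n, 3, 60)
    h <- runif(n, 3, 60)
    cx <- runif(n, w / 2, W - w / 2)
    cy <- runif(n, h / 2, H - h / 2)
    tibble::tibble(class = "fish", cx = cx, cy = cy, w = w, h = h,
                   difficult = FALSE)
  })
}

random_boxes <- function(n, lim = 100, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(cx = runif(n, 10, lim - 10), cy = runif(n, 10, lim - 10),
                   w = runif(n, 1, 30), h = runif(n, 1, 30))
  })
}

# loop-wise rectangle-sum AP oracle (counting, suffix max, explicit area)
ap_oracle <- function(flags, n_gt) {
  n <- length(flags)
  prec <- rec <- numeric(n)
  tp <- 0
  for (i in seq_len(n)) {
    if (flags[i]) tp <- tp + 1
    prec[i] <- tp / i
    rec[i] <- tp / n_gt
  }
  env <- numeric(n)
  for (i in seq_len(n)) env[i] <- max(prec[i:n])
  area <- 0
  prev <- 0
  for (i in seq_len(n)) {
    area <- area + (rec[i] - prev) * env[i]
    prev <- rec[i]
  }
  area
}


# independent scalar evaluation of the CIoU chain (overlap, center distance,
# enclosing diagonal, aspect term), written loop-wise
ciou_reference <- function(p, g) {
  vapply(seq_len(nrow(p)), function(i) {
    ax1 <- p$cx[i] - p$w[i] / 2; ax2 <- p$cx[i] + p$w[i] / 2
    ay1 <- p$cy[i] - p$h[i] / 2; ay2 <- p$cy[i] + p$h[i] / 2
    bx1 <- g$cx[i] - g$w[i] / 2; bx2 <- g$cx[i] + g$w[i] / 2
    by1 <- g$cy[i] - g$h[i] / 2; by2 <- g$cy[i] + g$h[i] / 2
    inter <- max(0, min(ax2, bx2) - max(ax1, bx1)) *
      max(0, min(ay2, by2) - max(ay1, by1))
    uni <- p$w[i] * p$h[i] + g$w[i] * g$h[i] - inter
    io <- inter / uni
    rho2 <- (p$cx[i] - g$cx[i])^2 + (p$cy[i] - g$cy[i])^2
    c2 <- (max(ax2, bx2) - min(ax1, bx1))^2 + (max(ay2, by2) - min(ay1, by1))^2
    v <- 4 / pi^2 * (atan(g$w[i] / g$h[i]) - atan(p$w[i] / p$h[i]))^2
    alpha <- v / ((1 - io) + v + 1e-12)
    io - rho2 / max(c2, 1e-12) - alpha * v
  }, numeric(1))
}

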