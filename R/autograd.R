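# Reverse-mode automatic differentiation over dense R arrays.
#
# A tape records operation nodes in creation order (which is a topological
# order of the computation graph); ag_backward() walks it in reverse and
# accumulates gradients into the participating nodes.  Every op also works
# without a tape (tape = NULL), in which case plain arrays go in and out --
# that is the inference fast path, which stores nothing.
#
# Feature maps are (H, W, C) arrays, column-major; convolution is im2col +
# GEMM through the BLAS that R is linked against.

ag_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 512L)
  tp$n <- 0L
  tp
}

ag_record <- function(tape, val, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$backward <- backward
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

#' @noRd
ag_leaf <- function(tape, val) {
  if (is.null(tape)) return(val)
  ag_record(tape, val)
}

is_node <- function(x) is.environment(x)

vv <- function(x) if (is.environment(x)) x$val else x

ag_accum <- function(nd, g) {
  if (is_node(nd)) {
    if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
  }
  invisible(NULL)
}

# Run the backward sweep from a scalar loss node.
ag_backward <- function(tape, loss) {
  stopifnot(is_node(loss))
  loss$grad <- 1
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd)
  }
  invisible(NULL)
}

## ---- elementwise arithmetic -------------------------------------------------

ag_add <- function(tape, a, b) {
  val <- vv(a) + vv(b)
  if (is.null(tape)) return(val)
  ag_record(tape, val, function(nd) {
    ag_accum(a, nd$grad)
    ag_accum(b, nd$grad)
  })
}

ag_sub <- function(tape, a, b) {
  val <- vv(a) - vv(b)
  if (is.null(tape)) return(val)
  ag_record(tape, val, function(nd) {
    ag_accum(a, nd$grad)
    ag_accum(b, -nd$grad)
  })
}

ag_mul <- function(tape, a, b) {
  av <- vv(a); bv <- vv(b)
  val <- av * bv
  if (is.null(tape)) return(val)
  ag_record(tape, val, function(nd) {
    ag_accum(a, nd$grad * bv)
    ag_accum(b, nd$grad * av)
  })
}

ag_div <- function(tape, a, b) {
  av <- vv(a); bv <- vv(b)
  val <- av / bv
  if (is.null(tape)) return(val)
  ag_record(tape, val, function(nd) {
    ag_accum(a, nd$grad / bv)
    ag_accum(b, -nd$grad * av / (bv * bv))
  })
}

# a * k + c with constant k, c
ag_affine <- function(tape, a, k = 1, c = 0) {
  val <- vv(a) * k + c
  if (is.null(tape)) return(val)
  ag_record(tape, val, function(nd) ag_accum(a, nd$grad * k))
}

ag_square <- function(tape, a) {
  av <- vv(a)
  val <- av * av
  if (is.null(tape)) return(val)
  ag_record(tape, val, function(nd) ag_accum(a, 2 * nd$grad * av))
}

ag_atan <- function(tape, a) {
  av <- vv(a)
  val <- atan(av)
  if (is.null(tape)) return(val)
  ag_record(tape, val, function(nd) ag_accum(a, nd$grad / (1 + av * av)))
}

# elementwise max against a constant (subgradient: pass-through where a wins)
ag_pmax_const <- function(tape, a, k) {
  av <- vv(a)
  val <- pmax(av, k)
  if (is.null(tape)) return(val)
  mask <- av > k
  ag_record(tape, val, function(nd) ag_accum(a, nd$grad * mask))
}

ag_pmin_const <- function(tape, a, k) {
  av <- vv(a)
  val <- pmin(av, k)
  if (is.null(tape)) return(val)
  mask <- av < k
  ag_record(tape, val, function(nd) ag_accum(a, nd$grad * mask))
}

ag_sigmoid <- function(tape, a) {
  val <- sigmoid_(vv(a))
  if (is.null(tape)) return(val)
  ag_record(tape, val, function(nd) ag_accum(a, nd$grad * val * (1 - val)))
}

ag_silu <- function(tape, a) {
  av <- vv(a)
  s <- sigmoid_(av)
  val <- av * s
  if (is.null(tape)) return(val)
  ag_record(tape, val, function(nd) ag_accum(a, nd$grad * (s * (1 + av * (1 - s)))))
}

ag_sum <- function(tape, a) {
  av <- vv(a)
  val <- sum(av)
  if (is.null(tape)) return(val)
  dm <- dim(av) %||% length(av)
  ag_record(tape, val, function(nd) ag_accum(a, array(nd$grad, dm)))
}

ag_mean <- function(tape, a) {
  av <- vv(a)
  n <- length(av)
  val <- sum(av) / n
  if (is.null(tape)) return(val)
  dm <- dim(av) %||% n
  ag_record(tape, val, function(nd) ag_accum(a, array(nd$grad / n, dm)))
}

# sum of scalar nodes (and plain numbers)
ag_addn <- function(tape, terms) {
  val <- sum(vapply(terms, vv, numeric(1)))
  if (is.null(tape)) return(val)
  ag_record(tape, val, function(nd) {
    for (tm in terms) ag_accum(tm, nd$grad)
  })
}

## ---- linear algebra ---------------------------------------------------------

ag_matmul <- function(tape, a, b) {
  av <- vv(a); bv <- vv(b)
  val <- av %*% bv
  if (is.null(tape)) return(val)
  ag_record(tape, val, function(nd) {
    if (is_node(a)) ag_accum(a, tcrossprod(nd$grad, bv))
    if (is_node(b)) ag_accum(b, crossprod(av, nd$grad))
  })
}

# add a bias vector to the columns of a matrix (n x C) + (C)
ag_bias_cols <- function(tape, a, b) {
  av <- vv(a); bvec <- vv(b)
  val <- av + rep(bvec, each = nrow(av))
  if (is.null(tape)) return(val)
  ag_record(tape, val, function(nd) {
    ag_accum(a, nd$grad)
    ag_accum(b, colSums(nd$grad))
  })
}

ag_rbind2 <- function(tape, a, b) {
  av <- vv(a); bv <- vv(b)
  val <- rbind(av, bv)
  if (is.null(tape)) return(val)
  na <- nrow(av)
  ag_record(tape, val, function(nd) {
    ag_accum(a, nd$grad[seq_len(na), , drop = FALSE])
    ag_accum(b, nd$grad[-seq_len(na), , drop = FALSE])
  })
}

ag_rows <- function(tape, a, idx) {
  av <- vv(a)
  val <- av[idx, , drop = FALSE]
  if (is.null(tape)) return(val)
  ag_record(tape, val, function(nd) {
    g <- array(0, dim(av))
    g[idx, ] <- nd$grad
    ag_accum(a, g)
  })
}

# gather arbitrary elements of an array node by a linear-index matrix;
# returns a matrix shaped like `sel` (duplicated indices accumulate on the
# way back)
ag_gather <- function(tape, a, sel) {
  av <- vv(a)
  val <- av[sel]
  dim(val) <- dim(sel)
  if (is.null(tape)) return(val)
  ag_record(tape, val, function(nd) {
    agg <- rowsum(as.numeric(nd$grad), as.integer(sel))
    g <- array(0, dim(av))
    g[as.integer(rownames(agg))] <- agg
    ag_accum(a, g)
  })
}

# single column of a matrix node, as a plain vector
ag_col <- function(tape, a, j) {
  av <- vv(a)
  val <- av[, j]
  if (is.null(tape)) return(val)
  ag_record(tape, val, function(nd) {
    g <- array(0, dim(av))
    g[, j] <- nd$grad
    ag_accum(a, g)
  })
}

## ---- structural ops on (H, W, C) maps --------------------------------------

ag_concat_c <- function(tape, parts) {
  vals <- lapply(parts, vv)
  d1 <- dim(vals[[1]])
  cs <- vapply(vals, function(v) dim(v)[3], numeric(1))
  val <- array(unlist(vals, use.names = FALSE), dim = c(d1[1], d1[2], sum(cs)))
  if (is.null(tape)) return(val)
  ends <- cumsum(cs)
  starts <- c(1, head(ends, -1) + 1)
  ag_record(tape, val, function(nd) {
    for (i in seq_along(parts)) {
      ag_accum(parts[[i]], nd$grad[, , starts[i]:ends[i], drop = FALSE])
    }
  })
}

# channel slice
ag_channels <- function(tape, a, ch) {
  av <- vv(a)
  val <- av[, , ch, drop = FALSE]
  if (is.null(tape)) return(val)
  ag_record(tape, val, function(nd) {
    g <- array(0, dim(av))
    g[, , ch] <- nd$grad
    ag_accum(a, g)
  })
}

# nearest-neighbour 2x upsampling
ag_upsample2x <- function(tape, a) {
  av <- vv(a)
  d <- dim(av)
  ri <- rep(seq_len(d[1]), each = 2L)
  ci <- rep(seq_len(d[2]), each = 2L)
  val <- av[ri, ci, , drop = FALSE]
  if (is.null(tape)) return(val)
  ag_record(tape, val, function(nd) {
    g <- nd$grad
    o1 <- seq.int(1L, 2L * d[1], 2L); o2 <- o1 + 1L
    p1 <- seq.int(1L, 2L * d[2], 2L); p2 <- p1 + 1L
    ag_accum(a, g[o1, p1, , drop = FALSE] + g[o2, p1, , drop = FALSE] +
               g[o1, p2, , drop = FALSE] + g[o2, p2, , drop = FALSE])
  })
}

# pixel-slicing stem: (H, W, C) -> (H/2, W/2, 4C)
ag_focus_slice <- function(tape, a) {
  av <- vv(a)
  d <- dim(av)
  o1 <- seq.int(1L, d[1], 2L); o2 <- seq.int(2L, d[1], 2L)
  p1 <- seq.int(1L, d[2], 2L); p2 <- seq.int(2L, d[2], 2L)
  val <- array(c(av[o1, p1, , drop = FALSE], av[o2, p1, , drop = FALSE],
                 av[o1, p2, , drop = FALSE], av[o2, p2, , drop = FALSE]),
               dim = c(length(o1), length(p1), 4L * d[3]))
  if (is.null(tape)) return(val)
  ag_record(tape, val, function(nd) {
    g <- nd$grad
    C <- d[3]
    dx <- array(0, d)
    dx[o1, p1, ] <- g[, , 1:C, drop = FALSE]
    dx[o2, p1, ] <- g[, , (C + 1):(2 * C), drop = FALSE]
    dx[o1, p2, ] <- g[, , (2 * C + 1):(3 * C), drop = FALSE]
    dx[o2, p2, ] <- g[, , (3 * C + 1):(4 * C), drop = FALSE]
    ag_accum(a, dx)
  })
}

## ---- convolution ------------------------------------------------------------

.conv_idx_cache <- new.env(parent = emptyenv())

# Precomputed im2col linear-index matrix for a (H, W, C) input.
conv_im2col_idx <- function(H, W, C, k, stride, pad) {
  key <- paste(H, W, C, k, stride, pad, sep = "_")
  got <- .conv_idx_cache[[key]]
  if (!is.null(got)) return(got)
  Hp <- H + 2L * pad
  Wp <- W + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  oi <- rep(seq_len(Ho), times = Wo)
  oj <- rep(seq_len(Wo), each = Ho)
  base <- (oi - 1L) * stride + 1L + ((oj - 1L) * stride) * Hp
  di <- rep(seq_len(k) - 1L, times = k * C)
  dj <- rep(rep(seq_len(k) - 1L, each = k), times = C)
  dc <- rep(seq_len(C) - 1L, each = k * k)
  off <- di + dj * Hp + dc * (Hp * Wp)
  idx <- outer(base, off, `+`)
  res <- list(idx = idx, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp)
  .conv_idx_cache[[key]] <- res
  res
}

pad_hw <- function(x, pad, value = 0) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(value, dim = c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  xp[(pad + 1):(pad + d[1]), (pad + 1):(pad + d[2]), ] <- x
  xp
}

# 2-D convolution with bias.  w: (k, k, Cin, Cout), b: (Cout).
ag_conv2d <- function(tape, x, w, b, stride = 1L, pad = NULL) {
  xv <- vv(x); wv <- vv(w); bv <- vv(b)
  d <- dim(xv)
  k <- dim(wv)[1]
  Co <- dim(wv)[4]
  if (is.null(pad)) pad <- k %/% 2L
  stopifnot(dim(wv)[3] == d[3])
  ii <- conv_im2col_idx(d[1], d[2], d[3], k, as.integer(stride), as.integer(pad))
  xp <- pad_hw(xv, pad)
  col <- xp[ii$idx]
  dim(col) <- dim(ii$idx)
  wm <- matrix(wv, ncol = Co)
  y <- col %*% wm
  y <- y + rep(bv, each = nrow(y))
  val <- array(y, dim = c(ii$Ho, ii$Wo, Co))
  if (is.null(tape)) return(val)
  ag_record(tape, val, function(nd) {
    dy <- matrix(nd$grad, nrow = ii$Ho * ii$Wo, ncol = Co)
    if (is_node(w)) {
      dw <- crossprod(col, dy)
      ag_accum(w, array(dw, dim(wv)))
    }
    if (is_node(b)) ag_accum(b, colSums(dy))
    if (is_node(x)) {
      # transposed convolution: place dy on a zero-stuffed canvas and
      # correlate it with the flipped kernel (all GEMM, no scatter loops)
      Hc <- ii$Hp - k + 1L
      Wc <- ii$Wp - k + 1L
      canvas <- array(0, c(Hc + 2L * (k - 1L), Wc + 2L * (k - 1L), Co))
      canvas[(k - 1L) + seq.int(1L, by = stride, length.out = ii$Ho),
             (k - 1L) + seq.int(1L, by = stride, length.out = ii$Wo), ] <- nd$grad
      jj <- conv_im2col_idx(dim(canvas)[1], dim(canvas)[2], Co, k, 1L, 0L)
      col2 <- canvas[jj$idx]
      dim(col2) <- dim(jj$idx)
      wrot <- matrix(aperm(wv[k:1, k:1, , , drop = FALSE], c(1, 2, 4, 3)),
                     ncol = d[3])
      dxp <- col2 %*% wrot
      dim(dxp) <- c(ii$Hp, ii$Wp, d[3])
      if (pad > 0L) {
        dxp <- dxp[(pad + 1):(pad + d[1]), (pad + 1):(pad + d[2]), , drop = FALSE]
      }
      ag_accum(x, dxp)
    }
  })
}

# max pooling (used by the pyramid-pooling block), stride 1 padding k/2 default
ag_maxpool <- function(tape, x, k, stride = 1L, pad = NULL) {
  xv <- vv(x)
  d <- dim(xv)
  if (is.null(pad)) pad <- k %/% 2L
  ii <- conv_im2col_idx(d[1], d[2], 1L, k, as.integer(stride), as.integer(pad))
  xp <- pad_hw(xv, pad, value = -Inf)
  np <- ii$Hp * ii$Wp
  nout <- ii$Ho * ii$Wo
  out <- numeric(nout * d[3])
  argl <- integer(nout * d[3])
  for (cc in seq_len(d[3])) {
    colm <- xp[ii$idx + (cc - 1L) * np]
    dim(colm) <- dim(ii$idx)
    mi <- max.col(colm, ties.method = "first")
    sel <- cbind(seq_len(nout), mi)
    sl <- ((cc - 1L) * nout + 1L):(cc * nout)
    out[sl] <- colm[sel]
    argl[sl] <- ii$idx[sel] + (cc - 1L) * np
  }
  val <- array(out, dim = c(ii$Ho, ii$Wo, d[3]))
  if (is.null(tape)) return(val)
  ag_record(tape, val, function(nd) {
    g <- as.numeric(nd$grad)
    agg <- rowsum(g, argl)
    dxp <- numeric(np * d[3])
    dxp[as.integer(rownames(agg))] <- agg
    dim(dxp) <- c(ii$Hp, ii$Wp, d[3])
    if (pad > 0L) {
      dxp <- dxp[(pad + 1):(pad + d[1]), (pad + 1):(pad + d[2]), , drop = FALSE]
    }
    ag_accum(x, dxp)
  })
}

## ---- pooling / gating for coordinate attention ------------------------------

# sum over the width axis of (H, W, C), returning (H, C)
sum_over_w <- function(xv, d) {
  matrix(rowSums(matrix(aperm(xv, c(1, 3, 2)), d[1] * d[3], d[2])), d[1], d[3])
}

# sum over the height axis of (H, W, C), returning (W, C)
sum_over_h <- function(xv, d) {
  matrix(colSums(matrix(xv, d[1], d[2] * d[3])), d[2], d[3])
}

# mean over width: (H, W, C) -> (H, C)
ag_meanpool_w <- function(tape, x) {
  xv <- vv(x)
  d <- dim(xv)
  val <- sum_over_w(xv, d) / d[2]
  if (is.null(tape)) return(val)
  ag_record(tape, val, function(nd) {
    g <- nd$grad / d[2]
    ag_accum(x, aperm(array(g, c(d[1], d[3], d[2])), c(1, 3, 2)))
  })
}

# mean over height: (H, W, C) -> (W, C)
ag_meanpool_h <- function(tape, x) {
  xv <- vv(x)
  d <- dim(xv)
  val <- sum_over_h(xv, d) / d[1]
  if (is.null(tape)) return(val)
  ag_record(tape, val, function(nd) {
    g <- nd$grad / d[1]
    ag_accum(x, aperm(array(g, c(d[2], d[3], d[1])), c(3, 1, 2)))
  })
}

expand_h <- function(g, d) aperm(array(g, c(d[1], d[3], d[2])), c(1, 3, 2))
expand_w <- function(g, d) aperm(array(g, c(d[2], d[3], d[1])), c(3, 1, 2))

# x * gh * gw with gh: (H, C) and gw: (W, C) broadcast over the other axis
ag_gate_hw <- function(tape, x, gh, gw) {
  xv <- vv(x); ghv <- vv(gh); gwv <- vv(gw)
  d <- dim(xv)
  ghe <- expand_h(ghv, d)
  gwe <- expand_w(gwv, d)
  val <- xv * ghe * gwe
  if (is.null(tape)) return(val)
  ag_record(tape, val, function(nd) {
    g <- nd$grad
    ag_accum(x, g * ghe * gwe)
    if (is_node(gh)) ag_accum(gh, sum_over_w(g * xv * gwe, d))
    if (is_node(gw)) ag_accum(gw, sum_over_h(g * xv * ghe, d))
  })
}

## ---- losses -----------------------------------------------------------------

# binary cross-entropy on logits; target/weight are constant arrays
ag_bce_logits_sum <- function(tape, x, target, weight = 1) {
  xv <- vv(x)
  sp <- pmax(-xv, 0) + log1p(exp(-abs(xv)))     # softplus(-x), stable
  elem <- sp + (1 - target) * xv
  val <- sum(weight * elem)
  if (is.null(tape)) return(val)
  ag_record(tape, val, function(nd) {
    ag_accum(x, nd$grad * weight * (sigmoid_(xv) - target))
  })
}
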