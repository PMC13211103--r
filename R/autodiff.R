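#' @useDynLib stripedet, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# ------------------------------------------------------------------------
# Minimal reverse-mode computational graph.
#
# Every differentiable quantity is an `ad_node`: an environment holding a
# plain numeric array in $value and, after ad_backward(), the gradient of
# the scalar root with respect to it in $grad.  Operations record
# themselves on an `ad_tape`; running with tape = NULL evaluates forward
# only (inference).  Feature tensors use dim = c(B, C, H, W).
# ------------------------------------------------------------------------

ad_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$n <- 0L
  class(e) <- "ad_tape"
  e
}

#' Wrap a numeric array as a graph node
#'
#' @param value numeric array (any shape; scalars allowed).
#' @param tape an `ad_tape` to record on, or `NULL` for forward-only use.
#' @param parents list of parent nodes (internal).
#' @param backward function(grad) -> list of parent gradients (internal).
#' @return An `ad_node` environment with fields `value` and (after
#'   [ad_backward()]) `grad`.
#' @keywords internal
ad_node <- function(value, tape = NULL, parents = NULL, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  class(nd) <- "ad_node"
  if (!is.null(tape)) {
    n <- tape$n + 1L
    if (n > length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", n))
    tape$nodes[[n]] <- nd
    tape$n <- n
  }
  nd
}

is_node <- function(x) inherits(x, "ad_node")
nv <- function(x) if (is_node(x)) x$value else x

# Keep only node-parents; backward functions must return grads aligned with
# the full argument list, non-nodes are skipped at accumulation time.
ad_op <- function(tape, value, args, backward) {
  ad_node(value, tape, parents = args, backward = backward)
}

#' Backpropagate from a scalar root node
#'
#' Accumulates `$grad` on every node reachable from `root` through the tape.
#' @param root scalar `ad_node` (the loss).
#' @param tape the `ad_tape` the graph was recorded on.
#' @keywords internal
ad_backward <- function(root, tape) {
  if (tape$n == 0L) return(invisible(NULL))
  for (i in seq_len(tape$n)) tape$nodes[[i]]$grad <- NULL
  root$grad <- array(1, dim = dim(root$value) %||% 1L)
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backward)) next
    gs <- nd$backward(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (!is_node(p)) next
      g <- gs[[j]]
      if (is.null(g)) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

shaped <- function(g, v) {
  dv <- dim(v)
  if (!is.null(dv)) dim(g) <- dv
  g
}

# --- elementwise ---------------------------------------------------------

t_add <- function(a, b, tape = NULL) {
  ad_op(tape, nv(a) + nv(b), list(a, b),
        function(g) list(g, g))
}

t_sub <- function(a, b, tape = NULL) {
  ad_op(tape, nv(a) - nv(b), list(a, b),
        function(g) list(g, -g))
}

t_mul <- function(a, b, tape = NULL) {
  av <- nv(a); bv <- nv(b)
  ad_op(tape, av * bv, list(a, b),
        function(g) list(shaped(g * bv, av), shaped(g * av, bv)))
}

t_scale <- function(a, s, tape = NULL) {
  ad_op(tape, nv(a) * s, list(a), function(g) list(g * s))
}

t_relu <- function(a, tape = NULL) {
  av <- nv(a)
  pos <- av > 0
  ad_op(tape, av * pos, list(a), function(g) list(shaped(g * pos, av)))
}

t_sigmoid <- function(a, tape = NULL) {
  y <- 1 / (1 + exp(-nv(a)))
  ad_op(tape, y, list(a), function(g) list(shaped(g * y * (1 - y), y)))
}

t_exp <- function(a, tape = NULL) {
  y <- exp(nv(a))
  ad_op(tape, y, list(a), function(g) list(shaped(g * y, y)))
}

t_max2 <- function(a, b, tape = NULL) {
  av <- nv(a); bv <- nv(b)
  takea <- av >= bv           # ties routed to the first argument
  y <- ifelse(takea, av, bv)
  y <- shaped(y, av)
  ad_op(tape, y, list(a, b),
        function(g) list(shaped(g * takea, av), shaped(g * !takea, bv)))
}

# --- broadcasting gates --------------------------------------------------

# x: (B,C,H,W); gate: (B,C) matrix.  Broadcast over H,W: with batch-fastest
# layout a length-B*C vector recycles exactly over the spatial dims.
t_mul_channel <- function(x, gate, tape = NULL) {
  xv <- nv(x); gv <- nv(gate)
  d <- dim(xv)
  y <- xv * as.vector(gv)
  ad_op(tape, y, list(x, gate), function(g) {
    gx <- shaped(g * as.vector(gv), xv)
    gg <- matrix(rowSums(matrix(as.vector(g) * as.vector(xv),
                                nrow = d[1] * d[2])), d[1], d[2])
    list(gx, gg)
  })
}

expand_spatial <- function(s, d) {
  # s: (B,1,H,W) -> (B,C,H,W)
  aperm(array(as.vector(s), dim = c(d[1], d[3], d[4], d[2])), c(1, 4, 2, 3))
}

collapse_spatial <- function(g, d) {
  # sum over channels: (B,C,H,W) -> (B,1,H,W)
  r <- aperm(g, c(1, 3, 4, 2))
  dim(r) <- c(d[1] * d[3] * d[4], d[2])
  array(rowSums(r), dim = c(d[1], 1L, d[3], d[4]))
}

# x: (B,C,H,W); gate: (B,1,H,W)
t_mul_spatial <- function(x, gate, tape = NULL) {
  xv <- nv(x); gv <- nv(gate)
  d <- dim(xv)
  ge <- expand_spatial(gv, d)
  ad_op(tape, xv * ge, list(x, gate), function(g) {
    list(shaped(g * ge, xv), collapse_spatial(g * xv, d))
  })
}

# --- reductions over feature maps ---------------------------------------

# global average pool: (B,C,H,W) -> (B,C) matrix
t_gap <- function(x, tape = NULL) {
  xv <- nv(x)
  d <- dim(xv)
  nhw <- d[3] * d[4]
  y <- matrix(rowSums(matrix(as.vector(xv), nrow = d[1] * d[2])) / nhw,
              d[1], d[2])
  ad_op(tape, y, list(x), function(g) {
    list(array(as.vector(g) / nhw, dim = d))
  })
}

# global max pool: (B,C,H,W) -> (B,C) matrix
t_gmp <- function(x, tape = NULL) {
  xv <- nv(x)
  d <- dim(xv)
  m <- matrix(as.vector(xv), nrow = d[1] * d[2])
  which_max <- max.col(m, ties.method = "first")
  y <- matrix(m[cbind(seq_len(nrow(m)), which_max)], d[1], d[2])
  ad_op(tape, y, list(x), function(g) {
    gx <- array(0, dim = d)
    gm <- matrix(as.vector(gx), nrow = d[1] * d[2])
    gm[cbind(seq_len(nrow(gm)), which_max)] <- as.vector(g)
    list(array(as.vector(gm), dim = d))
  })
}

# mean over channels: (B,C,H,W) -> (B,1,H,W)
t_cmean <- function(x, tape = NULL) {
  xv <- nv(x)
  d <- dim(xv)
  y <- collapse_spatial(xv, d) / d[2]
  ad_op(tape, y, list(x), function(g) {
    list(expand_spatial(g, d) / d[2])
  })
}

# max over channels: (B,C,H,W) -> (B,1,H,W)
t_cmax <- function(x, tape = NULL) {
  xv <- nv(x)
  d <- dim(xv)
  p <- aperm(xv, c(1, 3, 4, 2))
  dim(p) <- c(d[1] * d[3] * d[4], d[2])
  wmax <- max.col(p, ties.method = "first")
  y <- array(p[cbind(seq_len(nrow(p)), wmax)], dim = c(d[1], 1L, d[3], d[4]))
  ad_op(tape, y, list(x), function(g) {
    gp <- matrix(0, nrow(p), d[2])
    gp[cbind(seq_len(nrow(p)), wmax)] <- as.vector(g)
    dim(gp) <- c(d[1], d[3], d[4], d[2])
    list(aperm(gp, c(1, 4, 2, 3)))
  })
}

# concatenate along the channel axis
t_concat_c <- function(xs, tape = NULL) {
  vals <- lapply(xs, nv)
  d1 <- dim(vals[[1]])
  cs <- vapply(vals, function(v) dim(v)[2], integer(1))
  y <- array(0, dim = c(d1[1], sum(cs), d1[3], d1[4]))
  off <- 0L
  for (i in seq_along(vals)) {
    y[, off + seq_len(cs[i]), , ] <- vals[[i]]
    off <- off + cs[i]
  }
  ad_op(tape, y, xs, function(g) {
    out <- vector("list", length(vals))
    off <- 0L
    for (i in seq_along(vals)) {
      gi <- g[, off + seq_len(cs[i]), , , drop = FALSE]
      dim(gi) <- dim(vals[[i]])
      out[[i]] <- gi
      off <- off + cs[i]
    }
    out
  })
}

# --- convolution and resampling -----------------------------------------

t_conv2d <- function(x, w, b, stride = 1L, padh = 0L, padw = 0L, tape = NULL) {
  xv <- nv(x); wv <- nv(w); bv <- nv(b)
  y <- conv2d_fw(xv, wv, bv, as.integer(stride),
                 as.integer(padh), as.integer(padw))
  ad_op(tape, y, list(x, w, b), function(g) {
    bw <- conv2d_bw(xv, wv, g, as.integer(stride),
                    as.integer(padh), as.integer(padw))
    list(bw$gx, bw$gw, bw$gb)
  })
}

# nearest-neighbour 2x upsampling
t_upsample2 <- function(x, tape = NULL) {
  xv <- nv(x)
  d <- dim(xv)
  ih <- rep(seq_len(d[3]), each = 2L)
  iw <- rep(seq_len(d[4]), each = 2L)
  y <- xv[, , ih, iw, drop = FALSE]
  ad_op(tape, y, list(x), function(g) {
    oh <- seq_len(d[3]) * 2L
    ow <- seq_len(d[4]) * 2L
    list(g[, , oh - 1L, ow - 1L, drop = FALSE] +
         g[, , oh - 1L, ow, drop = FALSE] +
         g[, , oh, ow - 1L, drop = FALSE] +
         g[, , oh, ow, drop = FALSE])
  })
}

# RoI align: x (B,C,H,W), rois N x 5 (0-based batch, x1,y1,x2,y2 in [0,1])
t_roi_align <- function(x, rois, oh = 7L, ow = 7L, tape = NULL) {
  xv <- nv(x)
  y <- roi_align_fw(xv, rois, as.integer(oh), as.integer(ow))
  ad_op(tape, y, list(x), function(g) {
    list(roi_align_bw(xv, rois, g, as.integer(oh), as.integer(ow)))
  })
}

# mean-pool each RoI patch to a vector: (N,C,oh,ow) -> (N,C)
t_roi_mean <- function(x, tape = NULL) {
  xv <- nv(x)
  d <- dim(xv)
  nhw <- d[3] * d[4]
  y <- matrix(rowSums(matrix(as.vector(xv), nrow = d[1] * d[2])) / nhw,
              d[1], d[2])
  ad_op(tape, y, list(x), function(g) {
    list(array(as.vector(g) / nhw, dim = d))
  })
}

# --- dense layers --------------------------------------------------------

# x: (N, in) matrix; w: (in, out); b: length out
t_linear <- function(x, w, b, tape = NULL) {
  xv <- nv(x); wv <- nv(w); bv <- nv(b)
  y <- xv %*% wv + matrix(bv, nrow(xv), length(bv), byrow = TRUE)
  ad_op(tape, y, list(x, w, b), function(g) {
    list(g %*% t(wv), t(xv) %*% g, colSums(g))
  })
}

# row-wise l2 normalization with an epsilon guard
t_l2norm_rows <- function(x, tape = NULL, eps = 1e-12) {
  xv <- nv(x)
  nrm <- sqrt(pmax(rowSums(xv^2), eps))
  y <- xv / nrm
  ad_op(tape, y, list(x), function(g) {
    # d(x/||x||) = (g - y * <y, g>) / ||x||
    list((g - y * rowSums(y * g)) / nrm)
  })
}

# reshape (B,K,H,W) -> (B*H*W, K) matrix, rows enumerate (b,h,w)
t_bhwc_matrix <- function(x, tape = NULL) {
  xv <- nv(x)
  d <- dim(xv)
  p <- aperm(xv, c(1, 3, 4, 2))
  dim(p) <- c(d[1] * d[3] * d[4], d[2])
  ad_op(tape, p, list(x), function(g) {
    dim(g) <- c(d[1], d[3], d[4], d[2])
    list(aperm(g, c(1, 4, 2, 3)))
  })
}

t_select_rows <- function(x, idx, tape = NULL) {
  xv <- nv(x)
  y <- xv[idx, , drop = FALSE]
  ad_op(tape, y, list(x), function(g) {
    gx <- matrix(0, nrow(xv), ncol(xv))
    for (i in seq_along(idx)) gx[idx[i], ] <- gx[idx[i], ] + g[i, ]
    list(gx)
  })
}

# weighted sum of scalar nodes
t_wsum <- function(xs, weights, tape = NULL) {
  vals <- vapply(xs, function(x) as.numeric(nv(x)), numeric(1))
  ad_op(tape, sum(vals * weights), xs, function(g) {
    lapply(weights, function(w) as.numeric(g) * w)
  })
}
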