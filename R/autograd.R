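# Reverse-mode automatic differentiation on a flat tape.
#
# Values are plain R arrays (feature maps use dim (C, H, W), channel fastest).
# A node is an environment holding $value, $grad and, while a tape is
# recording, a $backward closure that scatters the node's gradient onto the
# nodes it was computed from. Backward replays the tape in reverse creation
# order, so no explicit topological sort is needed.

.ag <- new.env(parent = emptyenv())
.ag$recording <- FALSE
.ag$nodes <- vector("list", 256L)
.ag$n <- 0L
.ag$pid <- 0L

#' Create a tape node
#'
#' Low-level constructor used by every differentiable operation. User code
#' normally only needs [ag_param()] and the `ag_*` operations.
#'
#' @param value numeric array or scalar held by the node.
#' @param backward function of the node's gradient that accumulates into its
#'   inputs, or `NULL` for leaves/constants.
#' @return an object of class `ag_node`.
#' @keywords internal
ag_node <- function(value, backward = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  if (.ag$recording && !is.null(backward)) {
    n$backward <- backward
    k <- .ag$n + 1L
    if (k > length(.ag$nodes)) {
      .ag$nodes <- c(.ag$nodes, vector("list", length(.ag$nodes)))
    }
    .ag$nodes[[k]] <- n
    .ag$n <- k
  }
  class(n) <- "ag_node"
  n
}

#' Create a trainable parameter
#'
#' Parameters persist across tape replays; their `$grad` fields accumulate
#' during [ag_backward()] and are consumed by the optimizer.
#'
#' @param value initial numeric array.
#' @return an object of class `ag_param` (also an `ag_node`).
#' @export
ag_param <- function(value) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  .ag$pid <- .ag$pid + 1L
  n$id <- .ag$pid
  class(n) <- c("ag_param", "ag_node")
  n
}

is_node <- function(x) inherits(x, "ag_node")

#' @keywords internal
ag_val <- function(x) if (is_node(x)) x$value else x

ag_acc <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

#' Evaluate an expression while recording a gradient tape
#'
#' Clears the tape, enables recording, evaluates `expr` (which typically
#' ends with a call to [ag_backward()]), then disables recording and frees
#' the tape. Returns the value of `expr`.
#'
#' @param expr expression building (and optionally differentiating) a graph.
#' @export
with_tape <- function(expr) {
  .ag$nodes <- vector("list", 256L)
  .ag$n <- 0L
  .ag$recording <- TRUE
  on.exit({
    .ag$recording <- FALSE
    .ag$nodes <- vector("list", 256L)
    .ag$n <- 0L
  })
  expr
}

#' Backpropagate from a scalar loss node
#'
#' Seeds the loss gradient with 1 and replays the active tape in reverse.
#' Must be called inside [with_tape()].
#'
#' @param loss an `ag_node` holding a scalar.
#' @export
ag_backward <- function(loss) {
  if (!.ag$recording) stop("ag_backward() must run inside with_tape()")
  v <- loss$value
  loss$grad <- if (is.null(dim(v))) rep(1, length(v)) else array(1, dim(v))
  if (.ag$n > 0L) {
    for (k in .ag$n:1L) {
      nd <- .ag$nodes[[k]]
      if (!is.null(nd$grad)) nd$backward(nd$grad)
    }
  }
  invisible(NULL)
}

#' Zero the gradients of a parameter list
#' @param params list of `ag_param` objects.
#' @export
ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- elementwise operations -------------------------------------------------

#' @rdname ag_ops
#' @export
ag_add <- function(a, b) {
  out <- ag_val(a) + ag_val(b)
  ag_node(out, backward = function(g) {
    if (is_node(a)) ag_acc(a, g)
    if (is_node(b)) ag_acc(b, g)
  })
}

#' Differentiable array operations
#'
#' Primitive operations recorded on the gradient tape: elementwise
#' arithmetic, activations, reshapes, reductions, matrix products and
#' softmaxes. Each accepts `ag_node` inputs (or plain arrays, treated as
#' constants) and returns an `ag_node`.
#'
#' @param a,b,x nodes or numeric arrays.
#' @param k,s plain numeric constants.
#' @name ag_ops
#' @keywords internal
NULL

#' @rdname ag_ops
#' @export
ag_mul <- function(a, b) {
  av <- ag_val(a); bv <- ag_val(b)
  ag_node(av * bv, backward = function(g) {
    if (is_node(a)) ag_acc(a, g * bv)
    if (is_node(b)) ag_acc(b, g * av)
  })
}

#' @rdname ag_ops
#' @export
ag_affine <- function(x, a, k) {
  # a * x + k with constant a, k
  xv <- ag_val(x)
  ag_node(a * xv + k, backward = function(g) if (is_node(x)) ag_acc(x, a * g))
}

#' @rdname ag_ops
#' @export
ag_mulc <- function(x, k) {
  xv <- ag_val(x)
  ag_node(xv * k, backward = function(g) if (is_node(x)) ag_acc(x, g * k))
}

#' @rdname ag_ops
#' @export
ag_relu <- function(x) {
  xv <- ag_val(x)
  mask <- xv > 0
  ag_node(xv * mask, backward = function(g) if (is_node(x)) ag_acc(x, g * mask))
}

#' @rdname ag_ops
#' @export
ag_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-ag_val(x)))
  ag_node(s, backward = function(g) if (is_node(x)) ag_acc(x, g * s * (1 - s)))
}

#' @rdname ag_ops
#' @export
ag_tanh <- function(x) {
  t <- tanh(ag_val(x))
  ag_node(t, backward = function(g) if (is_node(x)) ag_acc(x, g * (1 - t * t)))
}

#' @rdname ag_ops
#' @export
ag_log <- function(x) {
  xv <- ag_val(x)
  ag_node(log(xv), backward = function(g) if (is_node(x)) ag_acc(x, g / xv))
}

#' @rdname ag_ops
#' @export
ag_powc <- function(x, k) {
  xv <- ag_val(x)
  ag_node(xv^k, backward = function(g) {
    if (is_node(x)) ag_acc(x, g * k * xv^(k - 1))
  })
}

#' @rdname ag_ops
#' @export
ag_clip <- function(x, lo, hi) {
  xv <- ag_val(x)
  mask <- xv > lo & xv < hi
  ag_node(pmin(pmax(xv, lo), hi),
          backward = function(g) if (is_node(x)) ag_acc(x, g * mask))
}

#' @rdname ag_ops
#' @export
ag_div <- function(a, b) {
  av <- ag_val(a); bv <- ag_val(b)
  out <- av / bv
  ag_node(out, backward = function(g) {
    if (is_node(a)) ag_acc(a, g / bv)
    if (is_node(b)) ag_acc(b, -g * av / (bv * bv))
  })
}

# alpha * x + y with a scalar parameter alpha (the attention scale)
#' @rdname ag_ops
#' @export
ag_axpy <- function(alpha, x, y) {
  av <- ag_val(alpha); xv <- ag_val(x); yv <- ag_val(y)
  ag_node(av * xv + yv, backward = function(g) {
    if (is_node(alpha)) ag_acc(alpha, sum(g * xv))
    if (is_node(x)) ag_acc(x, av * g)
    if (is_node(y)) ag_acc(y, g)
  })
}

# ---- shape bookkeeping ------------------------------------------------------

#' @rdname ag_ops
#' @export
ag_reshape <- function(x, dims) {
  xv <- ag_val(x)
  olddim <- dim(xv)
  out <- xv
  dim(out) <- dims
  ag_node(out, backward = function(g) {
    if (is_node(x)) { dim(g) <- olddim; ag_acc(x, g) }
  })
}

# (C, H, W) array viewed as a (C, H*W) matrix
#' @rdname ag_ops
#' @export
ag_cmat <- function(x) {
  d <- dim(ag_val(x))
  ag_reshape(x, c(d[1], d[2] * d[3]))
}

#' Concatenate feature maps along the channel axis
#' @param xs list of nodes/arrays shaped (C_i, H, W).
#' @export
ag_concat_c <- function(xs) {
  vals <- lapply(xs, ag_val)
  dims <- lapply(vals, dim)
  H <- dims[[1]][2]; W <- dims[[1]][3]
  cs <- vapply(dims, `[`, numeric(1), 1)
  # channel is the fastest axis, so build via (HW, C) transposes
  mats <- lapply(vals, function(v) t(matrix(v, nrow = dim(v)[1])))
  out <- t(do.call(cbind, mats))
  dim(out) <- c(sum(cs), H, W)
  ends <- cumsum(cs); starts <- ends - cs + 1
  ag_node(out, backward = function(g) {
    gm <- matrix(g, nrow = sum(cs))
    for (i in seq_along(xs)) {
      if (is_node(xs[[i]])) {
        gi <- gm[starts[i]:ends[i], , drop = FALSE]
        dim(gi) <- dims[[i]]
        ag_acc(xs[[i]], gi)
      }
    }
  })
}

#' Extract one channel of a (C, H, W) map as an (H, W) matrix
#' @param x node or array shaped (C, H, W).
#' @param k channel index (1-based).
#' @export
ag_slice_channel <- function(x, k) {
  xv <- ag_val(x)
  d <- dim(xv)
  out <- xv[k, , ]
  dim(out) <- d[2:3]
  ag_node(out, backward = function(g) {
    if (is_node(x)) {
      gx <- array(0, d)
      gx[k, , ] <- g
      ag_acc(x, gx)
    }
  })
}

# ---- reductions -------------------------------------------------------------

#' @rdname ag_ops
#' @export
ag_sum <- function(x) {
  xv <- ag_val(x)
  d <- dim(xv)
  ag_node(sum(xv), backward = function(g) {
    if (is_node(x)) {
      gx <- if (is.null(d)) rep(g, length(xv)) else array(g, d)
      ag_acc(x, gx)
    }
  })
}

# ---- matrix products --------------------------------------------------------

#' @rdname ag_ops
#' @param ta,tb transpose flags for the left/right operand.
#' @export
ag_matmul <- function(a, b, ta = FALSE, tb = FALSE) {
  av <- ag_val(a); bv <- ag_val(b)
  out <- if (!ta && !tb) av %*% bv
  else if (ta && !tb) crossprod(av, bv)
  else if (!ta && tb) tcrossprod(av, bv)
  else t(bv %*% av)
  ag_node(out, backward = function(g) {
    if (is_node(a)) {
      ga <- if (!ta && !tb) tcrossprod(g, bv)
      else if (ta && !tb) tcrossprod(bv, g)
      else if (!ta && tb) g %*% bv
      else t(g %*% bv)
      ag_acc(a, ga)
    }
    if (is_node(b)) {
      gb <- if (!ta && !tb) crossprod(av, g)
      else if (ta && !tb) av %*% g
      else if (!ta && tb) crossprod(g, av)
      else t(av %*% g)
      ag_acc(b, gb)
    }
  })
}

# ---- softmaxes --------------------------------------------------------------

#' @rdname ag_ops
#' @export
ag_softmax_rows <- function(x) {
  xv <- ag_val(x)
  e <- exp(xv - apply(xv, 1, max))
  s <- e / rowSums(e)
  ag_node(s, backward = function(g) {
    if (is_node(x)) {
      gs <- g * s
      ag_acc(x, gs - s * rowSums(gs))
    }
  })
}

# softmax over the channel axis of a (C, H, W) map, per pixel
#' @rdname ag_ops
#' @export
ag_softmax_channels <- function(x) {
  xv <- ag_val(x)
  d <- dim(xv)
  m <- matrix(xv, nrow = d[1])
  e <- exp(sweep(m, 2, apply(m, 2, max)))
  s <- sweep(e, 2, colSums(e), "/")
  out <- s
  dim(out) <- d
  ag_node(out, backward = function(g) {
    if (is_node(x)) {
      gm <- matrix(g, nrow = d[1])
      gs <- gm * s
      gx <- gs - sweep(s, 2, colSums(gs), "*")
      dim(gx) <- d
      ag_acc(x, gx)
    }
  })
}

# ---- convolution ------------------------------------------------------------

#' 2D convolution of a (C, H, W) map
#'
#' Implemented as im2col followed by one matrix product. Weights are stored
#' as a (C_out, C_in * kh * kw) matrix; zero padding keeps "same" spatial
#' size when `pad = floor(k / 2)` and `stride = 1`.
#'
#' @param x node or array (C_in, H, W).
#' @param w weight node, (C_out, C_in*kh*kw) matrix.
#' @param b bias node of length C_out, or `NULL`.
#' @param kh,kw kernel size.
#' @param stride stride.
#' @param pad zero padding.
#' @export
ag_conv2d <- function(x, w, b, kh, kw, stride = 1L, pad = 0L) {
  xv <- ag_val(x); wv <- ag_val(w)
  d <- dim(xv)
  C <- d[1]; H <- d[2]; W_ <- d[3]
  cols <- im2col_cpp(as.numeric(xv), C, H, W_, kh, kw, stride, pad)
  y <- wv %*% cols
  if (!is.null(b)) y <- y + ag_val(b)
  Ho <- (H + 2 * pad - kh) %/% stride + 1L
  Wo <- (W_ + 2 * pad - kw) %/% stride + 1L
  Cout <- nrow(wv)
  dim(y) <- c(Cout, Ho, Wo)
  ag_node(y, backward = function(g) {
    gm <- matrix(g, nrow = Cout)
    if (is_node(w)) ag_acc(w, tcrossprod(gm, cols))
    if (!is.null(b) && is_node(b)) ag_acc(b, rowSums(gm))
    if (is_node(x)) {
      gcols <- crossprod(wv, gm)
      ag_acc(x, col2im_cpp(gcols, C, H, W_, kh, kw, stride, pad))
    }
  })
}

# ---- pooling and resampling -------------------------------------------------

# memoized linear operators for pooling / bilinear resampling
.op_cache <- new.env(parent = emptyenv())

# (H*W x gh*gw) column-normalized averaging matrix for adaptive mean pooling
pool_matrix <- function(H, W, gh, gw) {
  key <- paste("P", H, W, gh, gw)
  if (!is.null(.op_cache[[key]])) return(.op_cache[[key]])
  hb <- floor(seq(0, H, length.out = gh + 1))
  wb <- floor(seq(0, W, length.out = gw + 1))
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  for (gj in seq_len(gw)) {
    for (gi in seq_len(gh)) {
      rows <- (hb[gi] + 1):hb[gi + 1]
      colsw <- (wb[gj] + 1):wb[gj + 1]
      pix <- as.vector(outer(rows, (colsw - 1) * H, "+"))
      cell <- (gj - 1) * gh + gi
      ii <- c(ii, pix); jj <- c(jj, rep(cell, length(pix)))
      vv <- c(vv, rep(1 / length(pix), length(pix)))
    }
  }
  P <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(H * W, gh * gw))
  .op_cache[[key]] <- P
  P
}

# list of pixel-index vectors per adaptive-pool cell (for max pooling)
pool_cells <- function(H, W, gh, gw) {
  key <- paste("cells", H, W, gh, gw)
  if (!is.null(.op_cache[[key]])) return(.op_cache[[key]])
  hb <- floor(seq(0, H, length.out = gh + 1))
  wb <- floor(seq(0, W, length.out = gw + 1))
  cells <- vector("list", gh * gw)
  for (gj in seq_len(gw)) {
    for (gi in seq_len(gh)) {
      rows <- (hb[gi] + 1):hb[gi + 1]
      colsw <- (wb[gj] + 1):wb[gj + 1]
      cells[[(gj - 1) * gh + gi]] <- as.vector(outer(rows, (colsw - 1) * H, "+"))
    }
  }
  .op_cache[[key]] <- cells
  cells
}

# 1D bilinear interpolation matrix (n_in x n_out), half-pixel centers
interp1d <- function(n_in, n_out) {
  scale <- n_in / n_out
  x <- (seq_len(n_out) - 0.5) * scale + 0.5
  x <- pmin(pmax(x, 1), n_in)
  i0 <- pmin(floor(x), n_in - 1L)
  if (n_in == 1L) i0 <- rep(1, n_out)
  tt <- x - i0
  i1 <- pmin(i0 + 1, n_in)
  Matrix::sparseMatrix(
    i = c(i0, i1), j = rep(seq_len(n_out), 2),
    x = c(1 - tt, tt), dims = c(n_in, n_out)
  )
}

# (H_in*W_in x H_out*W_out) separable bilinear operator
bilinear_matrix <- function(Hi, Wi, Ho, Wo) {
  key <- paste("B", Hi, Wi, Ho, Wo)
  if (!is.null(.op_cache[[key]])) return(.op_cache[[key]])
  U <- kronecker(interp1d(Wi, Wo), interp1d(Hi, Ho))
  .op_cache[[key]] <- U
  U
}

#' Adaptive average pooling onto a (gh, gw) grid
#' @param x node or array (C, H, W).
#' @param gh,gw output grid size.
#' @export
ag_pool_avg <- function(x, gh, gw = gh) {
  xv <- ag_val(x)
  d <- dim(xv)
  P <- pool_matrix(d[2], d[3], gh, gw)
  xm <- matrix(xv, nrow = d[1])
  y <- as.matrix(xm %*% P)
  dim(y) <- c(d[1], gh, gw)
  ag_node(y, backward = function(g) {
    if (is_node(x)) {
      gm <- matrix(g, nrow = d[1])
      gx <- as.matrix(Matrix::tcrossprod(gm, P))
      dim(gx) <- d
      ag_acc(x, gx)
    }
  })
}

#' Adaptive max pooling onto a (gh, gw) grid
#' @inheritParams ag_pool_avg
#' @export
ag_pool_max <- function(x, gh, gw = gh) {
  xv <- ag_val(x)
  d <- dim(xv)
  C <- d[1]
  cells <- pool_cells(d[2], d[3], gh, gw)
  xm <- matrix(xv, nrow = C)
  y <- matrix(0, C, gh * gw)
  arg <- matrix(0L, C, gh * gw)
  for (k in seq_along(cells)) {
    sub <- xm[, cells[[k]], drop = FALSE]
    idx <- max.col(sub, ties.method = "first")
    y[, k] <- sub[cbind(seq_len(C), idx)]
    arg[, k] <- cells[[k]][idx]
  }
  dim(y) <- c(C, gh, gw)
  ag_node(y, backward = function(g) {
    if (is_node(x)) {
      gm <- matrix(g, nrow = C)
      gx <- matrix(0, C, d[2] * d[3])
      for (k in seq_along(cells)) {
        gx[cbind(seq_len(C), arg[, k])] <- gx[cbind(seq_len(C), arg[, k])] + gm[, k]
      }
      dim(gx) <- d
      ag_acc(x, gx)
    }
  })
}

#' Bilinear resampling of a (C, H, W) map to (C, Ho, Wo)
#' @param x node or array (C, H, W).
#' @param Ho,Wo target spatial size.
#' @export
ag_resize_bilinear <- function(x, Ho, Wo) {
  xv <- ag_val(x)
  d <- dim(xv)
  U <- bilinear_matrix(d[2], d[3], Ho, Wo)
  xm <- matrix(xv, nrow = d[1])
  y <- as.matrix(xm %*% U)
  dim(y) <- c(d[1], Ho, Wo)
  ag_node(y, backward = function(g) {
    if (is_node(x)) {
      gm <- matrix(g, nrow = d[1])
      gx <- as.matrix(Matrix::tcrossprod(gm, U))
      dim(gx) <- d
      ag_acc(x, gx)
    }
  })
}
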