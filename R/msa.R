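# Multi-scale feature fusion attention (MSA) applied on skip connections:
# dual pyramid pooling (average + maximum branches over 1x1, 2x2, 4x4 and
# 6x6 grids) followed by position attention and channel attention, whose
# outputs are summed and projected back to the skip channel count.

#' Create an MSA module
#'
#' @param in_ch channel count C of the incoming skip feature map; must be
#'   divisible by `pool_reduce`.
#' @param out_ch channel count after the final projection (defaults to
#'   `in_ch` so the module is a drop-in on a skip connection).
#' @param grids pyramid grid sizes.
#' @param pool_reduce channel reduction factor of the 1x1 convolutions on
#'   each pooled map (the four reduced maps per branch stack back to C).
#' @param attn_ratio channel reduction ratio of the query/key projections
#'   in position attention.
#' @param max_attn_hw position attention computes the full pairwise map
#'   only up to this spatial size; larger maps are average-pooled down
#'   first (the pairwise map is quadratic in H*W).
#' @return an `msa_module` object.
#' @export
msa_module <- function(in_ch, out_ch = in_ch, grids = c(1L, 2L, 4L, 6L),
                       pool_reduce = 4L, attn_ratio = 8L, max_attn_hw = 32L) {
  if (in_ch %% pool_reduce != 0) {
    stop(sprintf("MSA input channels (%d) must be divisible by %d",
                 in_ch, pool_reduce))
  }
  red <- in_ch %/% pool_reduce
  fused <- 2L * in_ch
  qk <- max(1L, fused %/% attn_ratio)
  pool_convs <- function() lapply(grids, function(g) conv_layer(in_ch, red, k = 1L))
  structure(list(
    in_ch = in_ch, out_ch = out_ch, grids = as.integer(grids),
    pool_reduce = as.integer(pool_reduce), max_attn_hw = as.integer(max_attn_hw),
    avg_convs = pool_convs(),
    max_convs = pool_convs(),
    pa_b = conv_layer(fused, qk, k = 1L),
    pa_c = conv_layer(fused, qk, k = 1L),
    pa_d = conv_layer(fused, fused, k = 1L),
    alpha = ag_param(0),
    beta = ag_param(0),
    proj = conv_layer(fused, out_ch, k = 1L)
  ), class = "msa_module")
}

#' Dual pyramid pooling
#'
#' For each grid size g and each pool type (average, maximum): pool the
#' input onto a g-by-g grid, project from C to C/4 channels with a learned
#' 1x1 convolution, and upsample back to (H, W). The four average maps and
#' the four maximum maps are each stacked to C channels, the two stacks are
#' summed, and the result is concatenated with the input, giving 2C
#' channels.
#'
#' @param mod an [msa_module()].
#' @param x node or array (C, H, W) with H, W >= the largest grid.
#' @return node (2C, H, W).
#' @export
pyramid_pool <- function(mod, x) {
  d <- dim(ag_val(x))
  gmax <- max(mod$grids)
  if (d[2] < gmax || d[3] < gmax) {
    stop(sprintf("spatial size %dx%d too small for a %dx%d pyramid grid",
                 d[2], d[3], gmax, gmax))
  }
  if (d[1] != mod$in_ch) stop("channel count does not match MSA module")
  branch <- function(pool_fn, convs) {
    maps <- lapply(seq_along(mod$grids), function(i) {
      g <- mod$grids[i]
      p <- pool_fn(x, g, g)
      ag_resize_bilinear(conv_forward(convs[[i]], p), d[2], d[3])
    })
    ag_concat_c(maps)
  }
  avg <- branch(ag_pool_avg, mod$avg_convs)
  mx <- branch(ag_pool_max, mod$max_convs)
  ag_concat_c(list(x, ag_add(avg, mx)))
}

#' Position (spatial) self-attention
#'
#' Projections B, C, D are 1x1 convolutions of the input A. The spatial
#' attention map S softmax-normalizes, for each output position j, the
#' similarities exp(B_i . C_j) over all positions i; the output is
#' `alpha * sum_i s_ji D_i + A_j`. With `alpha` at its initial value 0 the
#' output equals the input exactly.
#'
#' @param a node or array (C, H, W).
#' @param wb,wc,wd 1x1 [conv_layer()] projections for B, C and D.
#' @param alpha scalar `ag_param` scale (initialized to 0).
#' @param return_maps also return the attention map S?
#' @return node (C, H, W), or `list(out, S)` when `return_maps`.
#' @export
position_attention <- function(a, wb, wc, wd, alpha, return_maps = FALSE) {
  d <- dim(ag_val(a))
  Bm <- ag_cmat(conv_forward(wb, a))
  Cm <- ag_cmat(conv_forward(wc, a))
  Dm <- ag_cmat(conv_forward(wd, a))
  # L[j, i] = B_i . C_j, softmax over i for each fixed j
  L <- ag_matmul(Cm, Bm, ta = TRUE)
  S <- ag_softmax_rows(L)
  term <- ag_reshape(ag_matmul(Dm, S, tb = TRUE), d)
  out <- ag_axpy(alpha, term, a)
  if (return_maps) list(out = out, S = S) else out
}

#' Channel self-attention
#'
#' The channel attention map X softmax-normalizes, for each output channel
#' j, the similarities exp(A_i . A_j) over all channels i of the raw input
#' (no projections); the output is `beta * sum_i x_ji A_i + A_j`. With
#' `beta` at its initial value 0 the output equals the input exactly.
#'
#' @param a node or array (C, H, W).
#' @param beta scalar `ag_param` scale (initialized to 0).
#' @param return_maps also return the attention map X?
#' @return node (C, H, W), or `list(out, X)` when `return_maps`.
#' @export
channel_attention <- function(a, beta, return_maps = FALSE) {
  d <- dim(ag_val(a))
  Am <- ag_cmat(a)
  M <- ag_matmul(Am, Am, tb = TRUE)   # M[j, i] = A_j . A_i
  X <- ag_softmax_rows(M)
  term <- ag_reshape(ag_matmul(X, Am), d)
  out <- ag_axpy(beta, term, a)
  if (return_maps) list(out = out, X = X) else out
}

# position attention with the spatial-size guard: the N^2 pairwise map is
# computed on an average-pooled copy when H*W exceeds max_attn_hw^2, and
# the attention term is upsampled before the residual sum
msa_position_branch <- function(mod, f) {
  d <- dim(ag_val(f))
  if (d[2] * d[3] <= mod$max_attn_hw^2) {
    return(position_attention(f, mod$pa_b, mod$pa_c, mod$pa_d, mod$alpha))
  }
  gh <- min(d[2], mod$max_attn_hw); gw <- min(d[3], mod$max_attn_hw)
  fd <- ag_pool_avg(f, gh, gw)
  Bm <- ag_cmat(conv_forward(mod$pa_b, fd))
  Cm <- ag_cmat(conv_forward(mod$pa_c, fd))
  Dm <- ag_cmat(conv_forward(mod$pa_d, fd))
  S <- ag_softmax_rows(ag_matmul(Cm, Bm, ta = TRUE))
  term <- ag_reshape(ag_matmul(Dm, S, tb = TRUE), c(d[1], gh, gw))
  ag_axpy(mod$alpha, ag_resize_bilinear(term, d[2], d[3]), f)
}

#' Full MSA forward pass
#'
#' [pyramid_pool()] then position and channel attention applied in parallel
#' to the fused 2C map; the two branch outputs are combined by elementwise
#' mean (each branch is a residual off the same fused map, so at
#' initialization, alpha = beta = 0, the combination equals the fused map
#' itself) and projected back to the configured skip channel count with a
#' 1x1 convolution.
#'
#' @param mod an [msa_module()].
#' @param x node or array (C, H, W).
#' @return node (out_ch, H, W).
#' @export
msa_forward <- function(mod, x) {
  f <- pyramid_pool(mod, x)
  e_pos <- msa_position_branch(mod, f)
  e_chn <- channel_attention(f, mod$beta)
  conv_forward(mod$proj, ag_mulc(ag_add(e_pos, e_chn), 0.5))
}
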