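# Convolutional GRU over a slice sequence, and its bidirectional wrapper.
# All dense products of the textbook GRU are replaced by "same"-padded
# convolutions, so hidden states are feature maps with the spatial size of
# the input.

#' Create convolutional GRU parameters
#'
#' Six convolution kernels: input-to-hidden Wz, Wr, W (with biases bz, br,
#' b) and hidden-to-hidden Uz, Ur, U (bias-free), all sharing one kernel
#' size.
#'
#' @param in_ch input feature channels.
#' @param hidden_ch hidden state channels (defaults to `in_ch`).
#' @param k square kernel size.
#' @return a `gru_params` object.
#' @export
gru_params <- function(in_ch, hidden_ch = in_ch, k = 3L) {
  structure(list(
    in_ch = in_ch, hidden_ch = hidden_ch, k = as.integer(k),
    wz = conv_layer(in_ch, hidden_ch, k = k),
    wr = conv_layer(in_ch, hidden_ch, k = k),
    wc = conv_layer(in_ch, hidden_ch, k = k),
    uz = conv_layer(hidden_ch, hidden_ch, k = k, bias = FALSE),
    ur = conv_layer(hidden_ch, hidden_ch, k = k, bias = FALSE),
    uc = conv_layer(hidden_ch, hidden_ch, k = k, bias = FALSE)
  ), class = "gru_params")
}

#' One convolutional GRU step
#'
#' Gates: `z = sigmoid(Wz*x + Uz*h + bz)`, `r = sigmoid(Wr*x + Ur*h + br)`,
#' candidate `h~ = tanh(W*x + U*(r.h) + b)` and update
#' `h' = (1-z).h + z.h~`, where `*` is a same-padded convolution and `.`
#' elementwise multiplication.
#'
#' @param x_t input feature map node/array (C, H, W).
#' @param h_prev previous hidden state node/array (C_h, H, W).
#' @param p a [gru_params()].
#' @return hidden state node (C_h, H, W).
#' @export
gru_step <- function(x_t, h_prev, p) {
  dx <- dim(ag_val(x_t)); dh <- dim(ag_val(h_prev))
  if (!identical(dx[2:3], dh[2:3])) {
    stop("input and hidden state must be spatially aligned")
  }
  z <- ag_sigmoid(ag_add(conv_forward(p$wz, x_t), conv_forward(p$uz, h_prev)))
  r <- ag_sigmoid(ag_add(conv_forward(p$wr, x_t), conv_forward(p$ur, h_prev)))
  hc <- ag_tanh(ag_add(conv_forward(p$wc, x_t),
                       conv_forward(p$uc, ag_mul(r, h_prev))))
  ag_add(ag_mul(ag_affine(z, -1, 1), h_prev), ag_mul(z, hc))
}

#' Run a convolutional GRU over a sequence in one direction
#'
#' The initial hidden state is zero. States are always returned in the
#' original slice order, regardless of direction.
#'
#' @param seq list of T feature map nodes/arrays (C, H, W).
#' @param p a [gru_params()].
#' @param reverse process the sequence back-to-front?
#' @return list of T hidden state nodes in original slice order.
#' @export
run_direction <- function(seq, p, reverse = FALSE) {
  if (length(seq) == 0) stop("empty sequence")
  d <- dim(ag_val(seq[[1]]))
  h <- ag_node(array(0, c(p$hidden_ch, d[2], d[3])))
  idx <- if (reverse) rev(seq_along(seq)) else seq_along(seq)
  states <- vector("list", length(seq))
  for (t in idx) {
    h <- gru_step(seq[[t]], h, p)
    states[[t]] <- h
  }
  states
}

#' Bidirectional convolutional GRU
#'
#' Runs one GRU forward and one backward over the sequence and
#' concatenates the two hidden states per step along the channel axis,
#' yielding 2 C_h channels per output step.
#'
#' @param seq list of T feature map nodes/arrays (C, H, W).
#' @param p_fwd,p_bwd [gru_params()] for the two directions.
#' @return list of T nodes (2*C_h, H, W) in original slice order.
#' @export
bi_convgru <- function(seq, p_fwd, p_bwd) {
  f <- run_direction(seq, p_fwd, reverse = FALSE)
  b <- run_direction(seq, p_bwd, reverse = TRUE)
  lapply(seq_along(seq), function(t) ag_concat_c(list(f[[t]], b[[t]])))
}
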