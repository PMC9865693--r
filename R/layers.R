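# Convolution layers and parameter bookkeeping.

#' Create a 2D convolution layer
#'
#' Weights use He-normal initialization, biases start at zero. The layer is
#' a plain list; apply it with [conv_forward()].
#'
#' @param in_ch,out_ch channel counts.
#' @param k square kernel size.
#' @param stride stride.
#' @param pad zero padding (defaults to "same" for stride 1).
#' @param bias include a bias term?
#' @return a `conv_layer` object.
#' @export
conv_layer <- function(in_ch, out_ch, k = 3L, stride = 1L, pad = k %/% 2L,
                       bias = TRUE) {
  sd <- sqrt(2 / (in_ch * k * k))
  w <- ag_param(matrix(stats::rnorm(out_ch * in_ch * k * k, sd = sd), out_ch))
  b <- if (bias) ag_param(numeric(out_ch)) else NULL
  structure(list(w = w, b = b, k = as.integer(k), stride = as.integer(stride),
                 pad = as.integer(pad), in_ch = in_ch, out_ch = out_ch),
            class = "conv_layer")
}

#' Apply a convolution layer to a (C, H, W) feature map
#' @param layer a [conv_layer()].
#' @param x node or array (C, H, W).
#' @export
conv_forward <- function(layer, x) {
  d <- dim(ag_val(x))
  if (d[1] != layer$in_ch) {
    stop(sprintf("conv expects %d input channels, got %d", layer$in_ch, d[1]))
  }
  ag_conv2d(x, layer$w, layer$b, layer$k, layer$k, layer$stride, layer$pad)
}

#' Collect all trainable parameters in a nested model structure
#' @param x arbitrarily nested list of layers/parameters.
#' @return flat list of `ag_param` objects (deterministic order).
#' @export
collect_params <- function(x) {
  if (inherits(x, "ag_param")) return(list(x))
  if (is.list(x)) {
    out <- lapply(x, collect_params)
    return(do.call(c, out))
  }
  list()
}

#' Extract / restore parameter values of a model
#' @param model nested model structure.
#' @export
param_values <- function(model) {
  lapply(collect_params(model), function(p) p$value)
}

#' @rdname param_values
#' @param values list as returned by [param_values()].
#' @export
set_param_values <- function(model, values) {
  ps <- collect_params(model)
  if (length(ps) != length(values)) {
    stop("parameter count mismatch when restoring values")
  }
  for (i in seq_along(ps)) ps[[i]]$value <- values[[i]]
  invisible(model)
}
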