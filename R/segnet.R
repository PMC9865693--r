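# Full network: shared per-slice U-shaped CNN (residual encoder, MSA on
# the skip connections, upsample-and-concatenate decoder), a bidirectional
# convolutional GRU across the slice dimension, and a 1x1-convolution +
# softmax output head.

#' Network configuration
#'
#' @param input_channels channels of each input slice (grayscale: 1).
#' @param num_classes output classes (>= 2; default background/foreground).
#' @param widths channel counts of the five encoder skip levels at strides
#'   2, 4, 8, 16 and 32.
#' @param reduce integer factor dividing all widths (and the head width)
#'   for desk-scale experiments; 1 keeps the full-size network.
#' @param head_width decoder output channels per slice; this is also the
#'   hidden channel count of the recurrence, so the bidirectional GRU
#'   emits `2 * head_width` channels.
#' @param seq_len sequence length T.
#' @param msa_on_skips `"auto"` (apply MSA on every skip whose spatial size
#'   admits the largest pyramid grid) or an integer vector of skip levels
#'   (1 = shallowest).
#' @param gru_kernel kernel size of the recurrence convolutions.
#' @param threshold binarization threshold for the foreground probability.
#' @param seed seed used for parameter initialization.
#' @return a `network_config` list.
#' @export
network_config <- function(input_channels = 1L, num_classes = 2L,
                           widths = c(64L, 256L, 512L, 1024L, 2048L),
                           reduce = 1L, head_width = NULL, seq_len = 8L,
                           msa_on_skips = "auto", gru_kernel = 3L,
                           threshold = 0.5, seed = 42L) {
  if (length(widths) != 5) stop("exactly five skip levels are required")
  if (num_classes < 2) stop("num_classes must be >= 2")
  if (any(widths %% reduce != 0)) stop("reduce must divide all widths")
  w <- as.integer(widths %/% reduce)
  if (any(w %% 4 != 0)) stop("reduced widths must stay divisible by 4")
  if (is.null(head_width)) head_width <- max(4L, 64L %/% reduce)
  structure(list(input_channels = as.integer(input_channels),
                 num_classes = as.integer(num_classes),
                 widths = w, reduce = as.integer(reduce),
                 head_width = as.integer(head_width),
                 seq_len = as.integer(seq_len),
                 msa_on_skips = msa_on_skips,
                 gru_kernel = as.integer(gru_kernel),
                 threshold = threshold, seed = as.integer(seed)),
            class = "network_config")
}

bottleneck_block <- function(in_ch, out_ch, stride) {
  mid <- out_ch %/% 4L
  list(c1 = conv_layer(in_ch, mid, k = 1L),
       c2 = conv_layer(mid, mid, k = 3L, stride = stride),
       c3 = conv_layer(mid, out_ch, k = 1L),
       sc = conv_layer(in_ch, out_ch, k = 1L, stride = stride))
}

bottleneck_forward <- function(blk, x) {
  y <- ag_relu(conv_forward(blk$c1, x))
  y <- ag_relu(conv_forward(blk$c2, y))
  y <- conv_forward(blk$c3, y)
  ag_relu(ag_add(y, conv_forward(blk$sc, x)))
}

#' Build the full segmentation network
#'
#' Parameter initialization is seeded from `cfg$seed`, so two builds with
#' the same configuration are bit-identical.
#'
#' @param cfg a [network_config()].
#' @return a `seqseg_net` object (nested list of layers).
#' @export
build_network <- function(cfg = network_config()) {
  stopifnot(inherits(cfg, "network_config"))
  set.seed(cfg$seed)
  w <- cfg$widths
  encoder <- list(
    stem = conv_layer(cfg$input_channels, w[1], k = 7L, stride = 2L, pad = 3L),
    stages = list(bottleneck_block(w[1], w[2], 2L),
                  bottleneck_block(w[2], w[3], 2L),
                  bottleneck_block(w[3], w[4], 2L),
                  bottleneck_block(w[4], w[5], 2L))
  )
  msa <- lapply(seq_len(5), function(l) msa_module(w[l], out_ch = w[l]))
  decoder <- list(
    up = lapply(4:1, function(l) conv_layer(w[l + 1] + w[l], w[l], k = 3L)),
    final = conv_layer(w[1], cfg$head_width, k = 3L)
  )
  hw <- cfg$head_width
  structure(list(
    cfg = cfg,
    cnn = list(encoder = encoder, msa = msa, decoder = decoder),
    rnn = list(fwd = gru_params(hw, hw, k = cfg$gru_kernel),
               bwd = gru_params(hw, hw, k = cfg$gru_kernel)),
    head = conv_layer(2L * hw, cfg$num_classes, k = 1L),
    static_head = conv_layer(hw, cfg$num_classes, k = 1L)
  ), class = "seqseg_net")
}

#' @export
print.seqseg_net <- function(x, ...) {
  np <- sum(vapply(collect_params(x), function(p) length(p$value), numeric(1)))
  cat(sprintf("seqseg_net: widths (%s), head %d, T=%d, %s parameters\n",
              paste(x$cfg$widths, collapse = ", "), x$cfg$head_width,
              x$cfg$seq_len, format(np, big.mark = ",")))
  invisible(x)
}

#' Encode one slice into five skip feature maps
#'
#' Residual bottleneck encoder emitting maps of the configured widths at
#' strides 2, 4, 8, 16 and 32. The input spatial size must be divisible
#' by 32.
#'
#' @param net a [build_network()] model.
#' @param x slice node/array (C, H, W).
#' @return list of five nodes, shallowest first.
#' @export
encode <- function(net, x) {
  d <- dim(ag_val(x))
  if (d[2] %% 32 != 0 || d[3] %% 32 != 0) {
    stop(sprintf("input spatial size %dx%d must be divisible by 32", d[2], d[3]))
  }
  skips <- vector("list", 5)
  skips[[1]] <- ag_relu(conv_forward(net$cnn$encoder$stem, x))
  for (l in 1:4) {
    skips[[l + 1]] <- bottleneck_forward(net$cnn$encoder$stages[[l]], skips[[l]])
  }
  skips
}

msa_levels_for <- function(net, skips) {
  cfg <- net$cfg
  if (identical(cfg$msa_on_skips, "auto")) {
    gmax <- max(net$cnn$msa[[1]]$grids)
    which(vapply(skips, function(s) {
      d <- dim(ag_val(s)); d[2] >= gmax && d[3] >= gmax
    }, logical(1)))
  } else {
    as.integer(cfg$msa_on_skips)
  }
}

#' Decode skip maps back to input resolution
#'
#' Successive bilinear upsample-and-concatenate stages without any
#' cropping, ending at the full input resolution with `head_width`
#' channels. MSA is applied to the skip maps first (per configuration).
#'
#' @param net a [build_network()] model.
#' @param skips list of five skip nodes from [encode()].
#' @param use_msa apply the MSA modules on the skip connections?
#' @return node (head_width, H, W) at input resolution.
#' @export
decode <- function(net, skips, use_msa = TRUE) {
  lv <- if (use_msa) msa_levels_for(net, skips) else integer(0)
  sk <- lapply(seq_len(5), function(l) {
    if (l %in% lv) msa_forward(net$cnn$msa[[l]], skips[[l]]) else skips[[l]]
  })
  d <- sk[[5]]
  for (i in seq_along(net$cnn$decoder$up)) {  # levels 4, 3, 2, 1
    l <- 5 - i
    tgt <- dim(ag_val(sk[[l]]))
    up <- ag_resize_bilinear(d, tgt[2], tgt[3])
    d <- ag_relu(conv_forward(net$cnn$decoder$up[[i]],
                              ag_concat_c(list(up, sk[[l]]))))
  }
  d1 <- dim(ag_val(d))
  up <- ag_resize_bilinear(d, d1[2] * 2L, d1[3] * 2L)
  ag_relu(conv_forward(net$cnn$decoder$final, up))
}

cnn_forward <- function(net, x, use_msa = TRUE) {
  decode(net, encode(net, x), use_msa = use_msa)
}

#' Forward pass over a batch of slice sequences
#'
#' Every slice of every sequence passes through the same per-slice CNN;
#' each sequence's decoder outputs run through the bidirectional
#' convolutional GRU, and the concatenated states pass through a 1x1
#' convolution to `num_classes` followed by a per-pixel softmax. With
#' `use_recurrence = FALSE` the recurrence is bypassed and a static
#' per-slice head is used instead.
#'
#' @param net a [build_network()] model.
#' @param batch array (N, T, C, H, W), or the list returned by
#'   [make_batch()].
#' @param use_recurrence run the Bi-ConvGRU? (`FALSE` gives the
#'   recurrence-free ablation).
#' @return list with `probabilities` (N, T, num_classes, H, W) and
#'   `nodes` (per-sequence list of per-slice probability nodes).
#' @export
network_forward <- function(net, batch, use_recurrence = TRUE) {
  if (is.list(batch)) batch <- batch$data
  d <- dim(batch)
  if (length(d) != 5) stop("batch must be a 5D (N, T, C, H, W) array")
  N <- d[1]; Tn <- d[2]; C <- d[3]; H <- d[4]; W <- d[5]
  if (C != net$cfg$input_channels) stop("batch channel count does not match network")
  ncls <- net$cfg$num_classes
  probs <- array(0, c(N, Tn, ncls, H, W))
  nodes <- vector("list", N)
  for (n in seq_len(N)) {
    feats <- lapply(seq_len(Tn), function(t) {
      cnn_forward(net, array(batch[n, t, , , ], c(C, H, W)))
    })
    pn <- vector("list", Tn)
    if (use_recurrence) {
      states <- bi_convgru(feats, net$rnn$fwd, net$rnn$bwd)
      for (t in seq_len(Tn)) {
        pn[[t]] <- ag_softmax_channels(conv_forward(net$head, states[[t]]))
      }
    } else {
      for (t in seq_len(Tn)) {
        pn[[t]] <- ag_softmax_channels(conv_forward(net$static_head, feats[[t]]))
      }
    }
    for (t in seq_len(Tn)) probs[n, t, , , ] <- pn[[t]]$value
    nodes[[n]] <- pn
  }
  list(probabilities = probs, nodes = nodes)
}

#' Binarize predicted probabilities
#'
#' Foreground where the foreground-class probability strictly exceeds the
#' threshold (ties go to background). When `pad_counts` is given, padded
#' trailing positions of each sequence are dropped.
#'
#' @param probabilities array (N, T, num_classes, H, W) or (num_classes,
#'   H, W), or the list returned by [network_forward()].
#' @param threshold in (0, 1).
#' @param pad_counts optional integer vector of per-sequence trailing pad
#'   counts; padded positions are returned as `NA`.
#' @return binary array (N, T, H, W) (or (H, W)); `NA` at dropped padding.
#' @export
binarize <- function(probabilities, threshold = 0.5, pad_counts = NULL) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be inside (0, 1)")
  if (is.list(probabilities)) probabilities <- probabilities$probabilities
  d <- dim(probabilities)
  if (length(d) == 3) {
    return((probabilities[2, , ] > threshold) * 1)
  }
  if (length(d) != 5) stop("expected a (N, T, C, H, W) probability array")
  fg <- array(probabilities[, , 2, , ], d[c(1, 2, 4, 5)])
  out <- (fg > threshold) * 1
  if (!is.null(pad_counts)) {
    for (n in seq_len(d[1])) {
      if (pad_counts[n] > 0) {
        out[n, (d[2] - pad_counts[n] + 1):d[2], , ] <- NA
      }
    }
  }
  out
}

#' Predict a binary mask volume for one input volume
#'
#' Preprocesses the volume (keeping every slice), runs the network
#' sequence by sequence and reassembles a binary mask volume aligned with
#' the input.
#'
#' @param net a trained [build_network()] model.
#' @param vol a [volume3d()].
#' @param target_size spatial size slices are resized to before the
#'   network; the predicted masks are resized back.
#' @param threshold binarization threshold.
#' @return binary 3D array shaped like the input volume.
#' @export
predict_volume <- function(net, vol, target_size = NULL, threshold = NULL) {
  if (is.null(threshold)) threshold <- net$cfg$threshold
  dvol <- dim(vol$intensities)
  if (is.null(target_size)) {
    target_size <- c(max(32L, (dvol[2] %/% 32L) * 32L),
                     max(32L, (dvol[3] %/% 32L) * 32L))
  }
  slices <- split_and_filter(vol, keep_empty = TRUE)
  slices <- lapply(slices, function(s) {
    r <- resize_slice(s$image, s$mask, target_size)
    list(image = r$image, mask = r$mask, index = s$index)
  })
  seqs <- make_sequences(slices, net$cfg$seq_len)
  out <- array(0, dvol)
  for (sq in seqs) {
    fwd <- network_forward(net, array(sq$images, c(1, dim(sq$images))))
    bm <- binarize(fwd$probabilities, threshold)
    n_real <- net$cfg$seq_len - sq$pad_count
    for (t in seq_len(n_real)) {
      m <- matrix(bm[1, t, , ], target_size[1], target_size[2])
      back <- resize_slice(matrix(0, target_size[1], target_size[2]), m,
                           c(dvol[2], dvol[3]))
      out[sq$source_index + t - 1, , ] <- back$mask
    }
  }
  out
}

#' Save / load a network checkpoint
#'
#' A checkpoint is the network configuration plus the flat list of
#' parameter arrays.
#'
#' @param net a `seqseg_net`.
#' @param path checkpoint file path.
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(list(cfg = net$cfg, params = param_values(net)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  net <- build_network(ck$cfg)
  set_param_values(net, ck$params)
  net
}
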