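# Three-stage training: (1) per-slice CNN pretraining with a static head,
# (2) recurrence training with the CNN frozen, (3) joint fine-tuning at a
# smaller learning rate. SGD with momentum throughout; everything funnels
# through one seed.

#' Training configuration
#'
#' @param stage1 list: `iterations` (epochs over the training slices),
#'   `batch_size`, `lr`, `decay_every` (epochs between step decays),
#'   `decay_factor`.
#' @param stage2 list: `lr`, `max_epochs`, `patience` (early stop on the
#'   monitored loss).
#' @param stage3 list: `lr` (must be smaller than stage 2's), `max_epochs`,
#'   `patience`.
#' @param momentum SGD momentum.
#' @param optimizer `"sgd"` (momentum SGD, the staged protocol's default)
#'   or `"adam"`.
#' @param schedule_kind `"step"` (decay every `decay_every` epochs) or
#'   `"cosine"` (annealed from `lr` to `cosine_lr_min`).
#' @param cosine_lr_min minimum learning rate of the cosine schedule.
#' @param seed master seed for the run.
#' @return a `train_config` list.
#' @export
train_config <- function(stage1 = list(iterations = 120L, batch_size = 16L,
                                       lr = 0.01, decay_every = 10L,
                                       decay_factor = 0.5),
                         stage2 = list(lr = 0.01, max_epochs = 40L,
                                       patience = 10L),
                         stage3 = list(lr = 0.001, max_epochs = 40L,
                                       patience = 10L),
                         momentum = 0.9, optimizer = "sgd",
                         schedule_kind = "step",
                         cosine_lr_min = 1e-4, seed = 42L) {
  if (!optimizer %in% c("sgd", "adam")) {
    stop(sprintf("unknown optimizer '%s'", optimizer))
  }
  if (stage1$lr <= 0 || stage2$lr <= 0 || stage3$lr <= 0) {
    stop("stage learning rates must be positive")
  }
  if (stage3$lr >= stage2$lr) stop("stage 3 learning rate must be below stage 2's")
  if (!schedule_kind %in% c("step", "cosine")) {
    stop(sprintf("unknown schedule kind '%s'", schedule_kind))
  }
  structure(list(stage1 = stage1, stage2 = stage2, stage3 = stage3,
                 momentum = momentum, optimizer = optimizer,
                 schedule_kind = schedule_kind,
                 cosine_lr_min = cosine_lr_min, seed = as.integer(seed)),
            class = "train_config")
}

#' Learning-rate schedule
#'
#' Step decay multiplies the stage's base rate by `decay_factor` after
#' every `decay_every` rounds. The cosine schedule anneals from the base
#' rate down to `cosine_lr_min` over `total` rounds.
#'
#' @param cfg a [train_config()].
#' @param stage `"stage1"`, `"stage2"` or `"stage3"`.
#' @param step 0-based round index.
#' @param total total rounds (cosine schedule only).
#' @return learning rate.
#' @export
lr_schedule <- function(cfg, stage = "stage1", step = 0L, total = NULL) {
  if (step < 0) stop("step must be >= 0")
  lr0 <- cfg[[stage]]$lr
  if (cfg$schedule_kind == "cosine") {
    if (is.null(total)) stop("cosine schedule needs the total round count")
    return(cfg$cosine_lr_min +
             0.5 * (lr0 - cfg$cosine_lr_min) * (1 + cos(pi * step / total)))
  }
  de <- cfg$stage1$decay_every
  fac <- cfg$stage1$decay_factor
  lr0 * fac^(step %/% de)
}

#' SGD-with-momentum optimizer
#'
#' @param params list of `ag_param` objects to update.
#' @param momentum momentum coefficient.
#' @return optimizer state object.
#' @export
sgd_optimizer <- function(params, momentum = 0.9) {
  structure(list(params = params, momentum = momentum,
                 v = new.env(parent = emptyenv())), class = "sgd_optimizer")
}

#' @rdname sgd_optimizer
#' @param opt optimizer state.
#' @param lr learning rate for this step.
#' @export
sgd_step <- function(opt, lr) {
  for (p in opt$params) {
    if (is.null(p$grad)) next
    key <- as.character(p$id)
    v <- opt$v[[key]]
    v <- if (is.null(v)) -lr * p$grad else opt$momentum * v - lr * p$grad
    opt$v[[key]] <- v
    p$value <- p$value + v
  }
  invisible(opt)
}

#' Adam optimizer
#'
#' Adaptive-moment optimizer; useful for the compact desk-scale
#' experiments where plain SGD converges slowly.
#'
#' @inheritParams sgd_optimizer
#' @param beta1,beta2 moment decay rates.
#' @param eps numerical stabilizer.
#' @export
adam_optimizer <- function(params, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  structure(list(params = params, beta1 = beta1, beta2 = beta2, eps = eps,
                 m = new.env(parent = emptyenv()),
                 v = new.env(parent = emptyenv()),
                 t = new.env(parent = emptyenv())),
            class = "adam_optimizer")
}

#' @rdname adam_optimizer
#' @param opt optimizer state.
#' @param lr learning rate for this step.
#' @export
adam_step <- function(opt, lr) {
  for (p in opt$params) {
    if (is.null(p$grad)) next
    key <- as.character(p$id)
    tt <- if (is.null(opt$t[[key]])) 1L else opt$t[[key]] + 1L
    opt$t[[key]] <- tt
    g <- p$grad
    m <- if (is.null(opt$m[[key]])) (1 - opt$beta1) * g
         else opt$beta1 * opt$m[[key]] + (1 - opt$beta1) * g
    v <- if (is.null(opt$v[[key]])) (1 - opt$beta2) * g * g
         else opt$beta2 * opt$v[[key]] + (1 - opt$beta2) * g * g
    opt$m[[key]] <- m; opt$v[[key]] <- v
    mh <- m / (1 - opt$beta1^tt)
    vh <- v / (1 - opt$beta2^tt)
    p$value <- p$value - lr * mh / (sqrt(vh) + opt$eps)
  }
  invisible(opt)
}

make_optimizer <- function(kind, params, momentum) {
  switch(kind,
         sgd = sgd_optimizer(params, momentum),
         adam = adam_optimizer(params),
         stop(sprintf("unknown optimizer '%s'", kind)))
}

optimizer_step <- function(opt, lr) {
  if (inherits(opt, "adam_optimizer")) adam_step(opt, lr) else sgd_step(opt, lr)
}

# combined loss over one sequence: per-slice foreground probabilities are
# stacked into a (T, H, W) map and padded positions weighted out
sequence_loss_node <- function(net, sq, loss_cfg, use_recurrence = TRUE) {
  images <- sq$images
  di <- dim(images)
  fwd <- network_forward(net, array(images, c(1, di)),
                         use_recurrence = use_recurrence)
  fg <- lapply(fwd$nodes[[1]], function(p) {
    ag_reshape(ag_slice_channel(p, 2L), c(1L, di[3], di[4]))
  })
  pred <- ag_concat_c(fg)                       # (T, H, W)
  w <- array(sq$valid, dim(sq$masks))           # T recycles fastest
  combined_loss(pred, sq$masks, loss_cfg, weight = w)
}

slice_loss_node <- function(net, image, mask, loss_cfg) {
  feat <- cnn_forward(net, array(image, c(1L, dim(image))))
  p <- ag_softmax_channels(conv_forward(net$static_head, feat))
  combined_loss(ag_slice_channel(p, 2L), mask, loss_cfg)
}

#' Joint training loop on full sequences
#'
#' Cycles through the training sequences, one optimizer step per sequence,
#' at a fixed learning rate. Used for compact end-to-end experiments
#' (overfitting demonstrations, ablations); the staged protocol lives in
#' [train_three_stage()].
#'
#' @param net a [build_network()] model.
#' @param seqs list of `slice_sequence` objects with masks.
#' @param steps optimizer step count.
#' @param lr learning rate.
#' @param momentum SGD momentum (ignored by Adam).
#' @param optimizer `"adam"` (default here: it converges quickly at this
#'   scale) or `"sgd"`.
#' @param loss_cfg a [loss_config()].
#' @param use_recurrence train the full model (`TRUE`) or the
#'   recurrence-free variant (`FALSE`).
#' @param params parameters to update (default: all of them).
#' @return numeric vector of per-step training losses.
#' @export
train_joint <- function(net, seqs, steps = 100L, lr = 0.003, momentum = 0.9,
                        optimizer = "adam", loss_cfg = loss_config(),
                        use_recurrence = TRUE, params = NULL) {
  if (length(seqs) == 0) stop("empty training set")
  if (is.null(params)) {
    params <- if (use_recurrence) {
      collect_params(list(net$cnn, net$rnn, net$head))
    } else {
      collect_params(list(net$cnn, net$static_head))
    }
  }
  opt <- make_optimizer(optimizer, params, momentum)
  losses <- numeric(steps)
  for (s in seq_len(steps)) {
    sq <- seqs[[(s - 1L) %% length(seqs) + 1L]]
    losses[s] <- with_tape({
      l <- sequence_loss_node(net, sq, loss_cfg, use_recurrence)
      ag_zero_grad(params)
      ag_backward(l)
      l$value
    })
    optimizer_step(opt, lr)
  }
  losses
}

run_epochs <- function(net, seqs, val_seqs, params, cfg, stage, loss_cfg,
                       use_recurrence, log_fn = NULL) {
  opt <- make_optimizer(cfg$optimizer, params, cfg$momentum)
  scfg <- cfg[[stage]]
  max_ep <- if (!is.null(scfg$max_epochs)) scfg$max_epochs else scfg$iterations
  patience <- scfg$patience
  best <- Inf; wait <- 0L
  ep_loss <- numeric(0)
  monitor_seqs <- if (length(val_seqs) > 0) val_seqs else seqs
  for (ep in seq_len(max_ep)) {
    lr <- lr_schedule(cfg, stage, ep - 1L, total = max_ep)
    tot <- 0
    for (sq in seqs) {
      tot <- tot + with_tape({
        l <- sequence_loss_node(net, sq, loss_cfg, use_recurrence)
        ag_zero_grad(params)
        ag_backward(l)
        l$value
      })
      optimizer_step(opt, lr)
    }
    ep_loss <- c(ep_loss, tot / length(seqs))
    if (!is.null(log_fn)) log_fn(stage, ep, tot / length(seqs), lr)
    if (!is.null(patience)) {
      mon <- mean(vapply(monitor_seqs, function(sq) {
        as.numeric(sequence_loss_node(net, sq, loss_cfg, use_recurrence)$value)
      }, numeric(1)))
      if (mon < best - 1e-6) { best <- mon; wait <- 0L } else wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  ep_loss
}

#' Three-stage training procedure
#'
#' Stage 1 trains only the per-slice CNN (recurrence bypassed, static
#' segmentation head) on individual slices for the configured number of
#' iterations with step-decayed learning rate. Stage 2 freezes every CNN
#' parameter and trains the recurrence (and its class head) until the
#' monitored loss stops improving. Stage 3 unfreezes everything and
#' fine-tunes jointly at the smaller stage-3 learning rate.
#'
#' @param train_seqs list of training `slice_sequence` objects.
#' @param val_seqs optional validation sequences (monitored for early
#'   stopping in stages 2-3).
#' @param cfg a [train_config()].
#' @param net_cfg a [network_config()] (used when `net` is not supplied).
#' @param net optionally, an existing network to train.
#' @param loss_cfg a [loss_config()].
#' @param log_fn optional callback `function(stage, epoch, loss, lr)`.
#' @return list with `net` and `history` (one record per stage).
#' @export
train_three_stage <- function(train_seqs, val_seqs = list(),
                              cfg = train_config(),
                              net_cfg = network_config(), net = NULL,
                              loss_cfg = loss_config(), log_fn = NULL) {
  if (length(train_seqs) == 0) stop("empty training set")
  set.seed(cfg$seed)
  if (is.null(net)) net <- build_network(net_cfg)

  # ---- stage 1: static per-slice CNN ----------------------------------
  cnn_params <- collect_params(list(net$cnn, net$static_head))
  opt <- make_optimizer(cfg$optimizer, cnn_params, cfg$momentum)
  slices <- list()
  for (sq in train_seqs) {
    for (t in which(sq$valid == 1)) {
      d <- dim(sq$images)
      slices[[length(slices) + 1]] <-
        list(image = matrix(sq$images[t, 1, , ], d[3], d[4]),
             mask = matrix(sq$masks[t, , ], d[3], d[4]))
    }
  }
  s1 <- cfg$stage1
  stage1_loss <- numeric(s1$iterations)
  for (ep in seq_len(s1$iterations)) {
    lr <- lr_schedule(cfg, "stage1", ep - 1L, total = s1$iterations)
    ord <- sample(length(slices))
    tot <- 0
    for (bs in seq(1, length(ord), by = s1$batch_size)) {
      idx <- ord[bs:min(bs + s1$batch_size - 1, length(ord))]
      tot <- tot + with_tape({
        parts <- lapply(idx, function(i) {
          slice_loss_node(net, slices[[i]]$image, slices[[i]]$mask, loss_cfg)
        })
        l <- parts[[1]]
        if (length(parts) > 1) for (k in 2:length(parts)) l <- ag_add(l, parts[[k]])
        l <- ag_mulc(l, 1 / length(parts))
        ag_zero_grad(cnn_params)
        ag_backward(l)
        l$value
      }) * length(idx)
      optimizer_step(opt, lr)
    }
    stage1_loss[ep] <- tot / length(slices)
    if (!is.null(log_fn)) log_fn("stage1", ep, stage1_loss[ep], lr)
  }

  # ---- stage 2: recurrence only, CNN frozen ---------------------------
  rnn_params <- collect_params(list(net$rnn, net$head))
  cnn_before <- lapply(cnn_params, function(p) p$value)
  stage2_loss <- run_epochs(net, train_seqs, val_seqs, rnn_params, cfg,
                            "stage2", loss_cfg, TRUE, log_fn)
  frozen_ok <- all(vapply(seq_along(cnn_params), function(i) {
    identical(cnn_params[[i]]$value, cnn_before[[i]])
  }, logical(1)))

  # ---- stage 3: joint fine-tuning -------------------------------------
  all_params <- collect_params(list(net$cnn, net$rnn, net$head))
  stage3_loss <- run_epochs(net, train_seqs, val_seqs, all_params, cfg,
                            "stage3", loss_cfg, TRUE, log_fn)

  history <- list(
    stage1 = list(loss = stage1_loss),
    stage2 = list(loss = stage2_loss, cnn_frozen = frozen_ok),
    stage3 = list(loss = stage3_loss)
  )
  list(net = net, history = history)
}

#' Validate a model on labelled sequences
#'
#' Predicts each sequence, binarizes at the configured threshold, and
#' reports mean Dice, IoU and Hausdorff distance (padded positions
#' excluded; Hausdorff averaged over sequences where it is defined).
#'
#' @param net a trained model.
#' @param seqs labelled `slice_sequence` list.
#' @param threshold binarization threshold (default: network config).
#' @param use_recurrence evaluate the full model or the recurrence-free
#'   variant.
#' @return list with `dice_pct`, `iou_pct`, `hausdorff` and a per-sequence
#'   data frame.
#' @export
validate_model <- function(net, seqs, threshold = NULL, use_recurrence = TRUE) {
  if (length(seqs) == 0) stop("empty validation set")
  if (is.null(threshold)) threshold <- net$cfg$threshold
  per <- data.frame(sequence = seq_along(seqs), dice_pct = NA_real_,
                    iou_pct = NA_real_, hausdorff = NA_real_)
  for (i in seq_along(seqs)) {
    sq <- seqs[[i]]
    fwd <- network_forward(net, array(sq$images, c(1, dim(sq$images))),
                           use_recurrence = use_recurrence)
    bm <- binarize(fwd$probabilities, threshold)
    keep <- which(sq$valid == 1)
    d <- dim(sq$masks)
    pred <- array(bm[1, keep, , ], c(length(keep), d[2], d[3]))
    ref <- array(sq$masks[keep, , ], c(length(keep), d[2], d[3]))
    ov <- dice_iou(pred, ref)
    per$dice_pct[i] <- ov[["dice"]]
    per$iou_pct[i] <- ov[["iou"]]
    per$hausdorff[i] <- if (sum(pred) > 0 && sum(ref) > 0) {
      hausdorff_distance(pred, ref)
    } else NA_real_
  }
  list(dice_pct = mean(per$dice_pct), iou_pct = mean(per$iou_pct),
       hausdorff = if (all(is.na(per$hausdorff))) NA_real_
                   else mean(per$hausdorff, na.rm = TRUE),
       per_sequence = per)
}
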