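# Segmentation losses: soft Dice, focal, and their sum.
#
# All three accept either plain numeric arrays (returning a numeric scalar)
# or tape nodes (returning a scalar node), so the same code path serves
# evaluation and training.

#' Loss configuration
#'
#' @param focal_alpha balance weight for the positive (foreground) class,
#'   in (0, 1).
#' @param focal_gamma focusing exponent, >= 0; larger values down-weight
#'   easy pixels more strongly.
#' @param smooth small constant added to the Dice numerator and denominator
#'   so the loss is defined for empty masks.
#' @return a `loss_config` list.
#' @export
loss_config <- function(focal_alpha = 0.25, focal_gamma = 2, smooth = 1e-6) {
  if (focal_alpha <= 0 || focal_alpha >= 1) stop("focal_alpha must be in (0, 1)")
  if (focal_gamma < 0) stop("focal_gamma must be >= 0")
  if (smooth <= 0) stop("smooth must be > 0")
  structure(list(focal_alpha = focal_alpha, focal_gamma = focal_gamma,
                 smooth = smooth), class = "loss_config")
}

check_loss_inputs <- function(pred, target, weight) {
  pd <- dim(ag_val(pred)); td <- dim(target)
  pl <- length(ag_val(pred)); tl <- length(target)
  if (!isTRUE(all.equal(as.integer(pd), as.integer(td))) || pl != tl) {
    stop("prediction and target shapes differ")
  }
  if (!all(target %in% c(0, 1))) stop("target must be binary")
  if (!is.null(weight) && length(weight) != tl) {
    stop("weight shape differs from target")
  }
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(p*g) + s) / (sum(p) + sum(g) + s)` over the (optionally
#' weighted) pixels: 0 for perfect overlap, 1 for disjoint nonempty masks.
#'
#' @param pred_fg foreground-probability map (array or tape node), values
#'   in \[0, 1\].
#' @param target binary reference map, same shape.
#' @param cfg a [loss_config()].
#' @param weight optional validity weights (e.g. 0 for padded slices).
#' @return numeric scalar, or a scalar node when `pred_fg` is a node.
#' @export
dice_loss <- function(pred_fg, target, cfg = loss_config(), weight = NULL) {
  check_loss_inputs(pred_fg, target, weight)
  w <- if (is.null(weight)) 1 else weight
  was_node <- is_node(pred_fg)
  s_pg <- ag_sum(ag_mulc(pred_fg, target * w))
  s_p <- ag_sum(ag_mulc(pred_fg, w))
  s_g <- sum(target * w)
  num <- ag_affine(ag_mulc(s_pg, 2), 1, cfg$smooth)
  den <- ag_affine(s_p, 1, s_g + cfg$smooth)
  out <- ag_affine(ag_div(num, den), -1, 1)
  if (was_node) out else out$value
}

#' Focal loss
#'
#' Per-pixel `-alpha * y * (1-p)^gamma * log(p)
#' - (1-alpha) * (1-y) * p^gamma * log(1-p)`, averaged over the (weighted)
#' pixels. Predictions are clipped to \[1e-7, 1 - 1e-7\] before the logs.
#'
#' @inheritParams dice_loss
#' @export
focal_loss <- function(pred_fg, target, cfg = loss_config(), weight = NULL) {
  check_loss_inputs(pred_fg, target, weight)
  w <- if (is.null(weight)) {
    v <- ag_val(pred_fg)
    if (is.null(dim(v))) rep(1, length(v)) else array(1, dim(v))
  } else weight
  was_node <- is_node(pred_fg)
  eps <- 1e-7
  p <- ag_clip(pred_fg, eps, 1 - eps)
  q <- ag_affine(p, -1, 1) # 1 - p
  a <- cfg$focal_alpha; gam <- cfg$focal_gamma
  y <- target
  pos <- ag_mulc(ag_mul(ag_powc(q, gam), ag_log(p)), -a * y * w)
  neg <- ag_mulc(ag_mul(ag_powc(p, gam), ag_log(q)), -(1 - a) * (1 - y) * w)
  tot <- ag_sum(ag_add(pos, neg))
  out <- ag_mulc(tot, 1 / sum(w))
  if (was_node) out else out$value
}

#' Combined segmentation loss
#'
#' Exact sum of [dice_loss()] and [focal_loss()] on the same inputs.
#'
#' @inheritParams dice_loss
#' @export
combined_loss <- function(pred_fg, target, cfg = loss_config(), weight = NULL) {
  was_node <- is_node(pred_fg)
  d <- dice_loss(pred_fg, target, cfg, weight)
  f <- focal_loss(pred_fg, target, cfg, weight)
  if (was_node) ag_add(d, f) else d + f
}
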