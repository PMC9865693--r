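# Seeded synthetic phantoms emulating the statistics of sequential cardiac
# MRI around a single low-contrast target structure:
#   (1) slice-to-slice continuity of the target (smooth area profile plus a
#       small random walk of its center),
#   (2) large scale variation across slices,
#   (3) low contrast against distractor blobs, and
#   (4) foreground occupying well under ten percent of the pixels.

#' Phantom generator configuration
#'
#' @param n_slices number of slices (>= 1).
#' @param height,width slice size in pixels.
#' @param fg_max_fraction maximum foreground pixel fraction per slice;
#'   must stay below 0.10.
#' @param contrast foreground-background intensity gap in (0, 1\].
#' @param n_distractors non-target blobs per slice. Distractors are drawn
#'   independently per slice (they lack inter-slice continuity, emulating
#'   other tissue cross-sections entering and leaving the imaging plane)
#'   and never overlap the target mask.
#' @param noise_sd additive Gaussian noise level (clipped to \[0, 1\]).
#' @param jitter_sd per-slice random-walk step (pixels) of the target center.
#' @param seed RNG seed; the phantom is fully reproducible from it.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(n_slices = 24L, height = 64L, width = 64L,
                           fg_max_fraction = 0.08, contrast = 0.15,
                           n_distractors = 3L, noise_sd = 0.03,
                           jitter_sd = 0.6, seed = 1L) {
  if (n_slices < 1) stop("n_slices must be >= 1")
  if (fg_max_fraction >= 0.10) stop("fg_max_fraction must be < 0.10")
  if (fg_max_fraction <= 0) stop("fg_max_fraction must be positive")
  if (contrast <= 0 || contrast > 1) stop("contrast must be in (0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(n_slices = as.integer(n_slices), height = as.integer(height),
                 width = as.integer(width), fg_max_fraction = fg_max_fraction,
                 contrast = contrast, n_distractors = as.integer(n_distractors),
                 noise_sd = noise_sd, jitter_sd = jitter_sd,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

ellipse_mask <- function(H, W, cy, cx, a, b, theta) {
  dy <- matrix(seq_len(H) - cy, H, W)
  dx <- matrix(rep(seq_len(W) - cx, each = H), H, W)
  u <- (dy * cos(theta) + dx * sin(theta)) / a
  v <- (-dy * sin(theta) + dx * cos(theta)) / b
  (u * u + v * v) <= 1
}

#' Generate one phantom volume with mask
#'
#' The target is an ellipse whose area follows a half-sine profile across
#' slices (large scale variation) while its center performs a small random
#' walk (continuity). Distractor blobs at intensities within `contrast` of
#' the target are placed independently per slice, outside the target mask.
#'
#' @param cfg a [phantom_config()].
#' @return a [volume3d()] with mask and unit spacing.
#' @export
generate_phantom <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "phantom_config"))
  set.seed(cfg$seed)
  H <- cfg$height; W <- cfg$width; ns <- cfg$n_slices
  # 0.95 head-room keeps discretized areas strictly under the cap
  amax <- cfg$fg_max_fraction * H * W * 0.95
  # floor at a fifth of the peak area: keeps the end slices from doubling
  # in area between neighbours (continuity) while preserving a >3x scale
  # range across the volume
  amin <- max(12, 0.2 * amax)
  if (amax < amin + 1) {
    stop("requested foreground fraction is unreachable at this image size")
  }
  bg <- 0.40
  fg_int <- bg + cfg$contrast
  q <- stats::runif(1, 1.2, 1.8)      # aspect ratio, fixed per volume
  theta <- stats::runif(1, 0, pi)     # orientation, fixed per volume
  cy <- H / 2 + stats::runif(1, -H / 8, H / 8)
  cx <- W / 2 + stats::runif(1, -W / 8, W / 8)
  phases <- if (ns == 1) 0.5 else (seq_len(ns) - 0.5) / ns
  areas <- amin + (amax - amin) * sin(pi * phases)
  ints <- array(bg, c(ns, H, W))
  mask <- array(0, c(ns, H, W))
  for (i in seq_len(ns)) {
    a <- sqrt(areas[i] * q / pi)
    b <- a / q
    margin <- a + 2
    cy <- min(max(cy + stats::rnorm(1, sd = cfg$jitter_sd), margin), H - margin)
    cx <- min(max(cx + stats::rnorm(1, sd = cfg$jitter_sd), margin), W - margin)
    m <- ellipse_mask(H, W, cy, cx, a, b, theta)
    if (!any(m)) m[round(cy), round(cx)] <- TRUE
    img <- matrix(bg, H, W)
    img[m] <- fg_int
    for (k in seq_len(cfg$n_distractors)) {
      da <- sqrt(stats::runif(1, amin, amax / 2) / pi)
      db <- da * stats::runif(1, 0.6, 1)
      dm <- ellipse_mask(H, W, stats::runif(1, 1, H), stats::runif(1, 1, W),
                         da, db, stats::runif(1, 0, pi))
      dint <- fg_int + stats::runif(1, -cfg$contrast, cfg$contrast)
      img[dm & !m] <- min(max(dint, 0), 1)
    }
    if (cfg$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(H * W, sd = cfg$noise_sd), H, W)
    }
    ints[i, , ] <- pmin(pmax(img, 0), 1)
    mask[i, , ] <- as.numeric(m)
  }
  frac <- apply(mask, 1, mean)
  if (any(frac >= 0.10)) {
    stop("internal error: generated foreground fraction reached 10%")
  }
  volume3d(ints, mask = mask, spacing = c(1, 1, 1))
}

#' Generate a reproducible dataset of phantom volumes
#'
#' Per-volume seeds are derived from the master seed, so the dataset is
#' bit-identical across runs.
#'
#' @param n_volumes number of volumes (>= 1).
#' @param cfg a [phantom_config()] used for every volume (its `seed` field
#'   is replaced by the derived per-volume seed).
#' @param seed master seed.
#' @return list of [volume3d()] objects.
#' @export
generate_dataset <- function(n_volumes, cfg = phantom_config(), seed = cfg$seed) {
  if (n_volumes < 1) stop("n_volumes must be >= 1")
  set.seed(seed)
  vol_seeds <- sample.int(.Machine$integer.max - 1L, n_volumes)
  lapply(vol_seeds, function(s) {
    ci <- cfg
    ci$seed <- s
    generate_phantom(ci)
  })
}

#' Split volumes into training and validation sets (4:1)
#'
#' @param vols list of volumes.
#' @return list with `train` and `val` volume lists.
#' @export
split_train_val <- function(vols) {
  n <- length(vols)
  if (n < 1) stop("no volumes to split")
  n_train <- max(1L, round(0.8 * n))
  if (n_train == n) {
    if (n == 1) warning("single volume assigned to training; validation set empty")
    else warning("too few volumes for a 4:1 split; validation set empty")
  }
  list(train = vols[seq_len(n_train)],
       val = if (n_train < n) vols[(n_train + 1):n] else list())
}
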