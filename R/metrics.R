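# Evaluation metrics: Dice / IoU overlap percentages and the exact
# (maximum) Hausdorff distance between foreground point sets.

check_binary_pair <- function(pred, ref) {
  if (!identical(dim2(pred), dim2(ref))) stop("mask shapes differ")
  if (!all(pred %in% c(0, 1)) || !all(ref %in% c(0, 1))) {
    stop("masks must be binary (0/1)")
  }
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Dice and IoU overlap percentages
#'
#' Set-based Dice `2|P∩G| / (|P|+|G|)` and IoU `|P∩G| / |P∪G|`, both as
#' percentages. Two empty masks agree perfectly and return (100, 100).
#'
#' @param pred,ref binary masks of identical shape (any dimensionality).
#' @return named numeric vector `c(dice = ..., iou = ...)`.
#' @export
dice_iou <- function(pred, ref) {
  check_binary_pair(pred, ref)
  np <- sum(pred); ng <- sum(ref)
  if (np == 0 && ng == 0) return(c(dice = 100, iou = 100))
  inter <- sum(pred * ref)
  c(dice = 200 * inter / (np + ng),
    iou = 100 * inter / (np + ng - inter))
}

# directed max-min distance from point set A to B (rows are points),
# computed in blocks to bound memory
directed_hausdorff <- function(A, B) {
  rb <- rowSums(B * B)
  worst <- 0
  n <- nrow(A)
  step <- 512L
  for (s in seq(1, n, by = step)) {
    e <- min(s + step - 1L, n)
    Ab <- A[s:e, , drop = FALSE]
    d2 <- outer(rowSums(Ab * Ab), rb, "+") - 2 * tcrossprod(Ab, B)
    worst <- max(worst, max(apply(d2, 1, min)))
  }
  sqrt(max(worst, 0))
}

#' Hausdorff distance between two binary masks
#'
#' Exact symmetric Hausdorff distance between the foreground voxel-center
#' coordinate sets under Euclidean distance. Coordinates are 1-based array
#' indices, optionally scaled per axis by `spacing` (mm per voxel).
#'
#' @param pred,ref binary masks of identical shape.
#' @param spacing optional per-axis physical voxel size.
#' @return distance in pixels (or mm when `spacing` is given); `NA` with a
#'   warning when either mask is empty.
#' @export
hausdorff_distance <- function(pred, ref, spacing = NULL) {
  check_binary_pair(pred, ref)
  if (sum(pred) == 0 || sum(ref) == 0) {
    warning("Hausdorff distance undefined for an empty mask")
    return(NA_real_)
  }
  da <- dim2(pred)
  A <- which(pred != 0) |> arrayInd(.dim = da)
  B <- which(ref != 0) |> arrayInd(.dim = da)
  storage.mode(A) <- "double"; storage.mode(B) <- "double"
  if (!is.null(spacing)) {
    if (length(spacing) != ncol(A)) stop("spacing length must match mask rank")
    if (any(spacing <= 0)) stop("spacing must be strictly positive")
    A <- sweep(A, 2, spacing, "*")
    B <- sweep(B, 2, spacing, "*")
  }
  max(directed_hausdorff(A, B), directed_hausdorff(B, A))
}

#' Evaluate a predicted volume against a reference volume
#'
#' Dice and IoU are pooled over all voxels of the volume; the Hausdorff
#' distance is computed between the 3D foreground point sets. A per-slice
#' breakdown (slices along the first axis) is included.
#'
#' @param pred_vol,ref_vol aligned binary 3D arrays (slice, row, col).
#' @param spacing optional per-axis physical voxel size (mm).
#' @return a `metric_report`: list with `dice_pct`, `iou_pct`, `hausdorff`
#'   and a `per_slice` data frame.
#' @export
evaluate_volume <- function(pred_vol, ref_vol, spacing = NULL) {
  check_binary_pair(pred_vol, ref_vol)
  ov <- dice_iou(pred_vol, ref_vol)
  hd <- suppressWarnings(hausdorff_distance(pred_vol, ref_vol, spacing))
  ns <- dim(pred_vol)[1]
  per <- data.frame(slice = seq_len(ns), dice_pct = NA_real_, iou_pct = NA_real_)
  for (i in seq_len(ns)) {
    s <- dice_iou(pred_vol[i, , ], ref_vol[i, , ])
    per$dice_pct[i] <- s[["dice"]]
    per$iou_pct[i] <- s[["iou"]]
  }
  structure(list(dice_pct = ov[["dice"]], iou_pct = ov[["iou"]],
                 hausdorff = hd, per_slice = per),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("Dice %.2f%%  IoU %.2f%%  Hausdorff %s\n",
              x$dice_pct, x$iou_pct,
              if (is.na(x$hausdorff)) "undefined" else sprintf("%.3f", x$hausdorff)))
  invisible(x)
}
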