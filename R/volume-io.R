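# Volume input/output and slice preprocessing.
#
# Internal convention: a volume is stored (slice, row, col) with the scan
# (slice-ordering) axis first. NIfTI files are read with RNifti; NRRD files
# with a small built-in parser (raw and gzip encodings).

#' Construct a 3D volume with optional mask
#'
#' @param intensities 3D numeric array (slice, row, col).
#' @param mask optional 3D binary array of identical shape. Values coded
#'   0/255 are remapped to 0/1.
#' @param spacing optional per-axis voxel size in mm (strictly positive).
#' @param scan_axis axis (1-based) of `intensities` that orders the slices;
#'   axes are permuted so it becomes the first.
#' @return a `volume3d` object.
#' @export
volume3d <- function(intensities, mask = NULL, spacing = NULL, scan_axis = 1L) {
  if (length(dim(intensities)) != 3) stop("intensities must be a 3D array")
  if (!scan_axis %in% 1:3) stop("scan_axis must be 1, 2 or 3")
  if (scan_axis != 1L) {
    perm <- c(scan_axis, setdiff(1:3, scan_axis))
    intensities <- aperm(intensities, perm)
    if (!is.null(mask)) mask <- aperm(mask, perm)
    if (!is.null(spacing)) spacing <- spacing[perm]
  }
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(intensities))) {
      stop(sprintf("mask shape (%s) does not match intensities (%s)",
                   paste(dim(mask), collapse = "x"),
                   paste(dim(intensities), collapse = "x")))
    }
    u <- unique(as.vector(mask))
    if (!all(u %in% c(0, 1, 255))) {
      stop("mask values must be coded 0/1 or 0/255")
    }
    mask <- array(as.numeric(mask != 0), dim(mask))
  }
  if (!is.null(spacing)) {
    if (length(spacing) != 3 || any(spacing <= 0)) {
      stop("spacing must be 3 strictly positive values")
    }
  }
  structure(list(intensities = intensities, mask = mask,
                 spacing = spacing, scan_axis = 1L),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("volume3d %s%s%s\n", paste(dim(x$intensities), collapse = "x"),
              if (is.null(x$mask)) ", no mask" else ", with mask",
              if (is.null(x$spacing)) "" else
                paste0(", spacing ", paste(signif(x$spacing, 4), collapse = "x"))))
  invisible(x)
}

is_nifti_path <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)
is_nrrd_path <- function(path) grepl("\\.nrrd$", path, ignore.case = TRUE)

read_any_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read volume: '%s' does not exist", path))
  if (is_nifti_path(path)) {
    img <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(img)
    arr <- array(as.numeric(img), dim(img))
    if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1L)
    sp <- if (length(sp) >= 3 && all(sp[1:3] > 0)) sp[1:3] else NULL
    list(data = arr, spacing = sp)
  } else if (is_nrrd_path(path)) {
    read_nrrd(path)
  } else {
    stop(sprintf("unsupported volume format: '%s' (expected .nii, .nii.gz or .nrrd)", path))
  }
}

#' Read a NRRD file
#'
#' Minimal NRRD reader covering the common scalar case: attached header,
#' `raw` or `gzip` encoding, little-endian, types uchar/short/ushort/int/
#' float/double, up to 3 dimensions.
#'
#' @param path path to a `.nrrd` file.
#' @return list with `data` (numeric array) and `spacing` (or `NULL`).
#' @export
read_nrrd <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  hdr_end <- which(bytes[-length(bytes)] == as.raw(10) & bytes[-1] == as.raw(10))
  if (length(hdr_end) == 0) stop("malformed NRRD: no blank line after header")
  hdr_end <- hdr_end[1]
  header <- strsplit(rawToChar(bytes[seq_len(hdr_end - 1)]), "\n")[[1]]
  header <- sub("\r$", "", header)
  if (!grepl("^NRRD000", header[1])) stop(sprintf("'%s' is not a NRRD file", path))
  fields <- list()
  for (line in header[-1]) {
    if (line == "" || grepl("^#", line)) next
    kv <- regmatches(line, regexpr(":=?", line), invert = TRUE)[[1]]
    fields[[trimws(tolower(kv[1]))]] <- trimws(kv[2])
  }
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  type <- fields$type
  enc <- fields$encoding
  n <- prod(sizes)
  payload <- bytes[(hdr_end + 2):length(bytes)]
  if (identical(enc, "gzip") || identical(enc, "gz")) {
    payload <- memDecompress(payload, type = "gzip")
  } else if (!identical(enc, "raw")) {
    stop(sprintf("unsupported NRRD encoding '%s'", enc))
  }
  reader <- switch(type,
    "uchar" = , "unsigned char" = , "uint8" = , "uint8_t" =
      function(r) as.numeric(readBin(r, "integer", n, size = 1, signed = FALSE)),
    "short" = , "int16" = , "int16_t" =
      function(r) as.numeric(readBin(r, "integer", n, size = 2, signed = TRUE,
                                     endian = "little")),
    "ushort" = , "uint16" = , "uint16_t" =
      function(r) as.numeric(readBin(r, "integer", n, size = 2, signed = FALSE,
                                     endian = "little")),
    "int" = , "int32" = , "int32_t" =
      function(r) as.numeric(readBin(r, "integer", n, size = 4, endian = "little")),
    "float" = function(r) as.numeric(readBin(r, "numeric", n, size = 4,
                                             endian = "little")),
    "double" = function(r) readBin(r, "numeric", n, size = 8, endian = "little"),
    stop(sprintf("unsupported NRRD type '%s'", type))
  )
  data <- array(reader(payload), dim = sizes)
  spacing <- NULL
  if (!is.null(fields$spacings)) {
    spacing <- as.numeric(strsplit(fields$spacings, "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    spacing <- vapply(vecs, function(v) {
      sqrt(sum(as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])^2))
    }, numeric(1), USE.NAMES = FALSE)
  }
  if (!is.null(spacing) && (length(spacing) != length(sizes) || any(spacing <= 0))) {
    spacing <- NULL
  }
  list(data = data, spacing = spacing)
}

#' Load a volume (and optional mask) from disk
#'
#' Reads NIfTI (`.nii`, `.nii.gz`) or NRRD (`.nrrd`) files. Mask values
#' coded 0/255 are remapped to 0/1; voxel spacing is taken from the header
#' when available.
#'
#' @param path path to the intensity volume.
#' @param mask_path optional path to an aligned binary label volume.
#' @param scan_axis axis ordering the slices (default: first array axis).
#' @return a [volume3d()].
#' @export
load_volume <- function(path, mask_path = NULL, scan_axis = 1L) {
  vol <- read_any_volume(path)
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- read_any_volume(mask_path)
    mask <- m$data
  }
  volume3d(vol$data, mask = mask, spacing = vol$spacing, scan_axis = scan_axis)
}

#' Write a volume (or mask) to NIfTI
#'
#' @param data 3D numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing optional per-axis voxel size written to the header.
#' @export
write_nifti_volume <- function(data, path, spacing = NULL) {
  img <- RNifti::asNifti(data)
  if (!is.null(spacing)) RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Split a volume into ordered 2D slices, optionally dropping empty ones
#'
#' Slices are returned in scan order. During training, slices whose mask
#' contains no foreground are excluded; for inference set
#' `keep_empty = TRUE` to retain every slice. Intensities are min-max
#' normalized per volume to \[0, 1\].
#'
#' @param vol a [volume3d()].
#' @param keep_empty keep slices without foreground? Requires a mask when
#'   `FALSE`.
#' @param normalize apply per-volume min-max normalization?
#' @return list of slices, each `list(image, mask, index)` with `index` the
#'   slice's 1-based position in the volume.
#' @export
split_and_filter <- function(vol, keep_empty = FALSE, normalize = TRUE) {
  stopifnot(inherits(vol, "volume3d"))
  if (!keep_empty && is.null(vol$mask)) {
    stop("excluding empty slices requires a mask (or set keep_empty = TRUE)")
  }
  ints <- vol$intensities
  if (normalize) {
    rng <- range(ints)
    ints <- if (rng[2] > rng[1]) (ints - rng[1]) / (rng[2] - rng[1]) else ints * 0
  }
  ns <- dim(ints)[1]
  keep <- if (keep_empty) rep(TRUE, ns)
          else vapply(seq_len(ns), function(i) sum(vol$mask[i, , ]) > 0, logical(1))
  if (!any(keep)) warning("volume contains no slices with foreground")
  lapply(which(keep), function(i) {
    list(image = matrix(ints[i, , ], dim(ints)[2], dim(ints)[3]),
         mask = if (is.null(vol$mask)) NULL else
           matrix(vol$mask[i, , ], dim(ints)[2], dim(ints)[3]),
         index = i)
  })
}

nearest_index <- function(n_in, n_out) {
  i <- ceiling((seq_len(n_out) - 0.5) * n_in / n_out)
  pmin(pmax(i, 1L), n_in)
}

#' Resize one slice (bilinear) and its mask (nearest-neighbour)
#'
#' @param img 2D numeric matrix.
#' @param mask optional binary matrix of identical shape.
#' @param target target size `c(H, W)`, each >= 8.
#' @return list with resized `image` and `mask`.
#' @export
resize_slice <- function(img, mask = NULL, target = c(512L, 512L)) {
  if (any(target <= 0)) stop("target size must be positive")
  if (any(target < 8)) stop("target size must be at least 8 pixels")
  d <- dim(img)
  if (!is.null(mask) && !identical(dim(mask), d)) stop("mask shape differs from image")
  if (identical(as.integer(d), as.integer(target))) {
    return(list(image = img, mask = mask))
  }
  U <- bilinear_matrix(d[1], d[2], target[1], target[2])
  out <- matrix(as.numeric(as.vector(img) %*% U), target[1], target[2])
  m <- NULL
  if (!is.null(mask)) {
    m <- mask[nearest_index(d[1], target[1]), nearest_index(d[2], target[2]),
              drop = FALSE]
  }
  list(image = out, mask = m)
}

#' Group ordered slices into fixed-length sequences
#'
#' Consecutive non-overlapping windows of length `T`; a final short window
#' is padded by repeating its last slice, with the number of padded
#' positions recorded so they can be excluded from losses and metrics.
#'
#' @param slices list of slices from [split_and_filter()].
#' @param seq_len window length T (>= 1).
#' @return list of `slice_sequence` objects with fields `images`
#'   (T, 1, H, W), `masks` (T, H, W) or NULL, `source_index`, `pad_count`
#'   and `valid` (1 for real positions, 0 for padding).
#' @export
make_sequences <- function(slices, seq_len = 8L) {
  if (length(slices) == 0) stop("cannot build sequences from an empty slice list")
  if (seq_len < 1) stop("sequence length must be >= 1")
  d <- dim(slices[[1]]$image)
  n <- length(slices)
  starts <- seq(1, n, by = seq_len)
  lapply(starts, function(s) {
    idx <- s:min(s + seq_len - 1, n)
    pad <- seq_len - length(idx)
    idx <- c(idx, rep(idx[length(idx)], pad))
    images <- array(0, c(seq_len, 1, d[1], d[2]))
    masks <- if (is.null(slices[[1]]$mask)) NULL else array(0, c(seq_len, d[1], d[2]))
    for (t in seq_len(seq_len)) {
      images[t, 1, , ] <- slices[[idx[t]]]$image
      if (!is.null(masks)) masks[t, , ] <- slices[[idx[t]]]$mask
    }
    structure(list(images = images, masks = masks,
                   source_index = slices[[s]]$index,
                   pad_count = pad,
                   valid = c(rep(1, seq_len - pad), rep(0, pad))),
              class = "slice_sequence")
  })
}

#' Stack sequences into a batch tensor
#' @param seqs list of `slice_sequence` objects sharing one shape.
#' @return list with `data` (N, T, C, H, W) and `masks` (N, T, H, W) or NULL.
#' @export
make_batch <- function(seqs) {
  if (length(seqs) == 0) stop("empty sequence list")
  d <- dim(seqs[[1]]$images)
  N <- length(seqs)
  data <- array(0, c(N, d))
  masks <- if (is.null(seqs[[1]]$masks)) NULL else array(0, c(N, d[1], d[3], d[4]))
  for (i in seq_len(N)) {
    data[i, , , , ] <- seqs[[i]]$images
    if (!is.null(masks)) masks[i, , , ] <- seqs[[i]]$masks
  }
  list(data = data, masks = masks)
}
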