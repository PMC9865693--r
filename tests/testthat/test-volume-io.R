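# Volume loading, slicing, resizing and sequence grouping.

test_that("NIfTI round trip preserves phantom data bit for bit", {
  vol <- generate_phantom(phantom_config(n_slices = 10, height = 64,
                                         width = 64, seed = 5))
  td <- withr::local_tempdir()
  ip <- file.path(td, "v.nii.gz"); mp <- file.path(td, "m.nii.gz")
  write_nifti_volume(vol$intensities, ip, vol$spacing)
  write_nifti_volume(vol$mask, mp, vol$spacing)
  back <- load_volume(ip, mp)
  expect_identical(dim(back$intensities), c(10L, 64L, 64L))
  expect_identical(as.vector(back$intensities), as.vector(vol$intensities))
  expect_identical(as.vector(back$mask), as.vector(vol$mask))
  expect_equal(back$spacing, c(1, 1, 1))
})

test_that("masks coded 0/255 are remapped and mismatches rejected", {
  ints <- array(runif(10 * 8 * 8), c(10, 8, 8))
  m255 <- array(0, c(10, 8, 8)); m255[3:7, 3:5, 3:5] <- 255
  v <- volume3d(ints, m255)
  expect_setequal(unique(as.vector(v$mask)), c(0, 1))
  expect_error(volume3d(ints, array(0, c(9, 8, 8))), "mask shape")
  expect_error(volume3d(ints, array(7, c(10, 8, 8))), "0/255")
  expect_error(volume3d(ints, m255, spacing = c(1, -1, 1)), "spacing")
})

test_that("missing files and unknown formats produce clear errors", {
  expect_error(load_volume("/nonexistent/vol.nii.gz"), "does not exist")
  tf <- withr::local_tempfile(fileext = ".xyz")
  writeLines("x", tf)
  expect_error(load_volume(tf), "unsupported volume format")
})

test_that("the NRRD reader handles raw and gzip encodings with spacing", {
  td <- withr::local_tempdir()
  arr <- array(as.numeric(1:24), c(2, 3, 4))
  write_fixture <- function(path, encoding) {
    payload <- writeBin(as.vector(arr), raw(), size = 8, endian = "little")
    if (encoding == "gzip") payload <- memCompress(payload, "gzip")
    hdr <- c("NRRD0004", "type: double", "dimension: 3", "sizes: 2 3 4",
             paste0("encoding: ", encoding), "endian: little",
             "spacings: 0.5 1.0 2.0", "")
    con <- file(path, "wb")
    writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
    writeBin(payload, con)
    close(con)
  }
  for (enc in c("raw", "gzip")) {
    p <- file.path(td, paste0("t_", enc, ".nrrd"))
    write_fixture(p, enc)
    got <- read_nrrd(p)
    expect_equal(got$data, arr)
    expect_equal(got$spacing, c(0.5, 1, 2))
  }
  vol <- load_volume(file.path(td, "t_raw.nrrd"))
  expect_identical(dim(vol$intensities), c(2L, 3L, 4L))
})

test_that("empty-slice exclusion matches a direct per-slice loop", {
  ints <- array(runif(10 * 16 * 16), c(10, 16, 16))
  mask <- array(0, c(10, 16, 16))
  mask[4:8, 5:9, 5:9] <- 1   # foreground only in slices 4..8 (1-based)
  vol <- volume3d(ints, mask)
  kept <- split_and_filter(vol, keep_empty = FALSE)
  expect_length(kept, 5)
  expect_equal(vapply(kept, `[[`, numeric(1), "index"), 4:8)
  # oracle: direct loop
  direct <- sum(vapply(1:10, function(i) sum(mask[i, , ]) > 0, logical(1)))
  expect_length(kept, direct)
  # inference mode keeps everything, even without a mask
  vol2 <- volume3d(ints)
  expect_length(split_and_filter(vol2, keep_empty = TRUE), 10)
  expect_error(split_and_filter(vol2, keep_empty = FALSE), "mask")
  # all-empty mask warns and returns nothing
  vol3 <- volume3d(ints, array(0, c(10, 16, 16)))
  expect_warning(res <- split_and_filter(vol3), "no slices")
  expect_length(res, 0)
})

test_that("slice intensities are min-max normalized per volume", {
  ints <- array(runif(4 * 8 * 8, 100, 900), c(4, 8, 8))
  vol <- volume3d(ints)
  slices <- split_and_filter(vol, keep_empty = TRUE)
  vals <- unlist(lapply(slices, `[[`, "image"))
  expect_equal(range(vals), c(0, 1))
})

test_that("resizing upsamples images smoothly and keeps masks binary", {
  set.seed(9)
  img <- matrix(runif(320 * 320), 320, 320)
  mask <- matrix(0, 320, 320); mask[100:150, 80:200] <- 1
  r <- resize_slice(img, mask, c(512, 512))
  expect_identical(dim(r$image), c(512L, 512L))
  expect_identical(dim(r$mask), c(512L, 512L))
  expect_setequal(unique(as.vector(r$mask)), c(0, 1))
  # identity when already at target
  r2 <- resize_slice(img, mask, c(320, 320))
  expect_identical(r2$image, img)
  expect_identical(r2$mask, mask)
  expect_error(resize_slice(img, mask, c(0, 512)), "positive")
  expect_error(resize_slice(img, mask, c(4, 4)), "at least 8")
})

test_that("sequence grouping covers every slice once with recorded padding", {
  mk <- function(n) {
    lapply(seq_len(n), function(i) {
      list(image = matrix(i, 8, 8), mask = matrix(1, 8, 8), index = i)
    })
  }
  s16 <- make_sequences(mk(16), 8)
  expect_length(s16, 2)
  expect_equal(vapply(s16, `[[`, numeric(1), "pad_count"), c(0, 0))
  s12 <- make_sequences(mk(12), 8)
  expect_length(s12, 2)
  expect_equal(s12[[2]]$pad_count, 4)
  expect_equal(s12[[2]]$valid, c(1, 1, 1, 1, 0, 0, 0, 0))
  s1 <- make_sequences(mk(1), 8)
  expect_equal(s1[[1]]$pad_count, 7)
  expect_error(make_sequences(list(), 8), "empty")
  expect_error(make_sequences(mk(3), 0), ">= 1")
  # unpadded concatenation reproduces the slice list exactly
  for (n in c(1, 5, 8, 12, 16, 17)) {
    seqs <- make_sequences(mk(n), 8)
    got <- unlist(lapply(seqs, function(sq) {
      vapply(which(sq$valid == 1), function(t) sq$images[t, 1, 1, 1], numeric(1))
    }))
    expect_equal(got, as.numeric(seq_len(n)))
  }
})

test_that("batches stack sequences in (N, T, C, H, W) order", {
  seqs <- tiny_sequences(seed = 3, n_slices = 8, size = 32, seq_len = 4)
  b <- make_batch(seqs)
  expect_identical(dim(b$data), c(length(seqs), 4L, 1L, 32L, 32L))
  expect_equal(b$data[2, 3, 1, , ], seqs[[2]]$images[3, 1, , ])
  expect_identical(dim(b$masks), c(length(seqs), 4L, 32L, 32L))
})

test_that("scan axis permutation puts slices first", {
  ints <- array(runif(6 * 8 * 10), c(6, 8, 10))
  v <- volume3d(aperm(ints, c(2, 3, 1)), scan_axis = 3)
  expect_identical(dim(v$intensities), c(6L, 8L, 10L))
  expect_equal(v$intensities, ints)
})
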