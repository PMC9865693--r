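# Network assembly: encoder widths/strides, decoder resolution recovery,
# forward-pass contracts, binarization.

test_that("the default encoder emits the five configured skip widths", {
  net <- build_network(network_config(seed = 61))
  x <- array(rnorm(1 * 64 * 64), c(1, 64, 64))
  skips <- encode(net, x)
  widths <- vapply(skips, function(s) dim(s$value)[1], numeric(1))
  expect_equal(widths, c(64, 256, 512, 1024, 2048))
  sizes <- vapply(skips, function(s) dim(s$value)[2], numeric(1))
  expect_equal(sizes, c(32, 16, 8, 4, 2))
  expect_error(encode(net, array(0, c(1, 60, 60))), "divisible by 32")
})

test_that("a reduced configuration scales all widths by the factor", {
  cfg <- network_config(reduce = 8, seed = 62)
  expect_equal(cfg$widths, c(8L, 32L, 64L, 128L, 256L))
  expect_error(network_config(widths = c(10, 20, 40, 80, 160), reduce = 5),
               "divisible by 4")
  expect_error(network_config(widths = c(64, 256, 512, 1024)), "five")
  expect_error(network_config(num_classes = 1), "num_classes")
})

test_that("the decoder returns to input resolution with the head width", {
  net <- tiny_network(seed = 63)
  x <- array(rnorm(1 * 32 * 32), c(1, 32, 32))
  out <- decode(net, encode(net, x))
  expect_identical(dim(out$value), c(net$cfg$head_width, 32L, 32L))
  # disabling MSA gives the plain U-shaped decoder: identical whenever the
  # configuration applies MSA on no level, and different when it does
  out_plain <- decode(net, encode(net, x), use_msa = FALSE)
  expect_identical(dim(out_plain$value), dim(out$value))
})

test_that("forward produces per-pixel probability simplexes and shares parameters", {
  net <- tiny_network(seed = 64)
  set.seed(64)
  batch <- array(runif(2 * 4 * 1 * 32 * 32), c(2, 4, 1, 32, 32))
  fwd <- network_forward(net, batch)
  expect_identical(dim(fwd$probabilities), c(2L, 4L, 2L, 32L, 32L))
  sums <- apply(fwd$probabilities, c(1, 2, 4, 5), sum)
  expect_lt(max(abs(sums - 1)), 1e-5)
  # permuting the batch axis permutes outputs identically
  fwd_perm <- network_forward(net, batch[c(2, 1), , , , , drop = FALSE])
  expect_equal(fwd_perm$probabilities[1, , , , ], fwd$probabilities[2, , , , ],
               tolerance = 1e-12)
  # duplicating one volume gives identical outputs in both slots
  dup <- batch; dup[2, , , , ] <- dup[1, , , , ]
  fwd_dup <- network_forward(net, dup)
  expect_equal(fwd_dup$probabilities[1, , , , ], fwd_dup$probabilities[2, , , , ],
               tolerance = 1e-12)
})

test_that("without the recurrence, per-slice outputs ignore slice order", {
  net <- tiny_network(seed = 65)
  set.seed(65)
  batch <- array(runif(1 * 4 * 1 * 32 * 32), c(1, 4, 1, 32, 32))
  fwd <- network_forward(net, batch, use_recurrence = FALSE)
  ord <- c(3, 1, 4, 2)
  fwd_sh <- network_forward(net, batch[, ord, , , , drop = FALSE],
                            use_recurrence = FALSE)
  expect_equal(fwd_sh$probabilities[1, , , , ], fwd$probabilities[1, ord, , , ],
               tolerance = 1e-12)
})

test_that("binarization applies a strict threshold and drops padding", {
  p <- array(0.5, c(1, 2, 2, 4, 4))
  p[, , 1, , ] <- 0.5
  expect_true(all(binarize(p, 0.5) == 0))     # ties go to background
  p1 <- array(0, c(1, 1, 2, 4, 4)); p1[, , 2, , ] <- 1
  expect_true(all(binarize(p1, 0.5) == 1))
  expect_error(binarize(p, 0), "threshold")
  expect_error(binarize(p, 1), "threshold")
  p2 <- array(runif(2 * 4 * 2 * 4 * 4), c(2, 4, 2, 4, 4))
  bm <- binarize(p2, 0.5, pad_counts = c(0, 2))
  expect_false(anyNA(bm[1, , , ]))
  expect_true(all(is.na(bm[2, 3:4, , ])))
  expect_false(anyNA(bm[2, 1:2, , ]))
})

test_that("checkpoints round-trip the configuration and parameters", {
  net <- tiny_network(seed = 66)
  td <- withr::local_tempdir()
  ck <- file.path(td, "net.rds")
  save_checkpoint(net, ck)
  net2 <- load_checkpoint(ck)
  expect_equal(net2$cfg, net$cfg)
  x <- array(runif(1 * 2 * 1 * 32 * 32), c(1, 2, 1, 32, 32))
  f1 <- network_forward(net, x)$probabilities
  f2 <- network_forward(net2, x)$probabilities
  expect_identical(f1, f2)
})

test_that("predict_volume reassembles a full-size binary mask volume", {
  vol <- generate_phantom(phantom_config(n_slices = 5, height = 32,
                                         width = 32, seed = 67))
  net <- tiny_network(seed = 67, seq_len = 2)
  out <- predict_volume(net, vol)
  expect_identical(dim(out), dim(vol$intensities))
  expect_true(all(out %in% c(0, 1)))
})
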