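# Convolutional GRU: gate-limit identities, reduction to the textbook
# dense GRU, direction symmetry and channel bookkeeping.

test_that("saturating the update gate selects candidate or previous state", {
  set.seed(31)
  p <- gru_params(2, 2)
  x <- array(rnorm(2 * 5 * 5), c(2, 5, 5))
  h <- array(rnorm(2 * 5 * 5), c(2, 5, 5))
  # z -> 1: output equals the candidate state
  p$wz$b$value <- rep(1e4, 2)
  h1 <- gru_step(x, h, p)$value
  r <- ag_sigmoid(ag_add(conv_forward(p$wr, x), conv_forward(p$ur, h)))
  hc <- ag_tanh(ag_add(conv_forward(p$wc, x),
                       conv_forward(p$uc, ag_mul(r, h))))$value
  expect_equal(h1, hc, tolerance = 1e-12)
  # z -> 0: output equals the previous state
  p$wz$b$value <- rep(-1e4, 2)
  expect_equal(gru_step(x, h, p)$value, h, tolerance = 1e-12)
})

test_that("all-zero parameters and state give the hand-derived zero output", {
  p <- gru_params(1, 1)
  for (lay in list(p$wz, p$wr, p$wc, p$uz, p$ur, p$uc)) {
    lay$w$value[] <- 0
    if (!is.null(lay$b)) lay$b$value[] <- 0
  }
  x <- array(rnorm(1 * 3 * 3), c(1, 3, 3))
  h0 <- array(0, c(1, 3, 3))
  # z = r = sigmoid(0) = 0.5, candidate = tanh(0) = 0, h = 0.5*0 + 0.5*0 = 0
  expect_equal(gru_step(x, h0, p)$value, h0)
})

test_that("gates stay in (0,1) and the candidate in (-1,1); shape preserved", {
  set.seed(32)
  p <- gru_params(3, 3)
  x <- array(rnorm(3 * 6 * 7), c(3, 6, 7))
  h <- array(rnorm(3 * 6 * 7), c(3, 6, 7))
  z <- ag_sigmoid(ag_add(conv_forward(p$wz, x), conv_forward(p$uz, h)))$value
  r <- ag_sigmoid(ag_add(conv_forward(p$wr, x), conv_forward(p$ur, h)))$value
  hc <- ag_tanh(ag_add(conv_forward(p$wc, x),
                       conv_forward(p$uc, ag_mul(r, h))))$value
  expect_true(all(z > 0 & z < 1))
  expect_true(all(r > 0 & r < 1))
  expect_true(all(hc > -1 & hc < 1))
  expect_identical(dim(gru_step(x, h, p)$value), c(3L, 6L, 7L))
})

test_that("a 1x1 ConvGRU reproduces an independent dense GRU to 1e-10", {
  set.seed(33)
  p <- gru_params(1, 1, k = 1)
  th <- rnorm(9, sd = 0.8)
  p$wz$w$value[] <- th[1]; p$uz$w$value[] <- th[2]; p$wz$b$value[] <- th[3]
  p$wr$w$value[] <- th[4]; p$ur$w$value[] <- th[5]; p$wr$b$value[] <- th[6]
  p$wc$w$value[] <- th[7]; p$uc$w$value[] <- th[8]; p$wc$b$value[] <- th[9]
  xs <- rnorm(20)
  seq_in <- lapply(xs, function(v) array(v, c(1, 1, 1)))
  got <- vapply(run_direction(seq_in, p), function(s) s$value[1, 1, 1], numeric(1))
  want <- dense_gru_scalar(xs, th[1], th[2], th[3], th[4], th[5], th[6],
                           th[7], th[8], th[9])
  expect_lt(max(abs(got - want)), 1e-10)
})

test_that("direction handling: T=1 symmetry and reversal equivalence", {
  set.seed(34)
  p <- gru_params(2, 2)
  one <- list(array(rnorm(2 * 4 * 4), c(2, 4, 4)))
  f <- run_direction(one, p, reverse = FALSE)
  b <- run_direction(one, p, reverse = TRUE)
  expect_equal(f[[1]]$value, b[[1]]$value)
  abc <- lapply(1:3, function(i) array(rnorm(2 * 4 * 4), c(2, 4, 4)))
  rev_run <- run_direction(abc, p, reverse = TRUE)
  fwd_on_flipped <- run_direction(rev(abc), p, reverse = FALSE)
  for (t in 1:3) {
    expect_equal(rev_run[[t]]$value, fwd_on_flipped[[4 - t]]$value)
  }
  expect_error(run_direction(list(), p), "empty")
})

test_that("constant input drives the state towards a fixed point", {
  set.seed(35)
  p <- gru_params(2, 2)
  x <- array(rnorm(2 * 4 * 4), c(2, 4, 4))
  states <- run_direction(rep(list(x), 12), p)
  dn <- vapply(2:12, function(t) {
    sqrt(sum((states[[t]]$value - states[[t - 1]]$value)^2))
  }, numeric(1))
  # differences shrink monotonically after the initial transient
  expect_true(all(diff(dn[3:11]) <= 1e-12))
})

test_that("the bidirectional wrapper concatenates to 2C channels", {
  set.seed(36)
  pf <- gru_params(8, 8); pb <- gru_params(8, 8)
  seq_in <- lapply(1:3, function(i) array(rnorm(8 * 4 * 4), c(8, 4, 4)))
  out <- bi_convgru(seq_in, pf, pb)
  expect_length(out, 3)
  for (o in out) expect_identical(dim(o$value), c(16L, 4L, 4L))
  # reversing the input and swapping parameter sets swaps the halves
  out_sw <- bi_convgru(rev(seq_in), pb, pf)
  for (t in 1:3) {
    a <- out[[t]]$value
    b <- out_sw[[4 - t]]$value
    expect_equal(a[1:8, , ], b[9:16, , ], tolerance = 1e-12)
    expect_equal(a[9:16, , ], b[1:8, , ], tolerance = 1e-12)
  }
})

test_that("palindromic input with shared parameters has symmetric halves", {
  set.seed(37)
  p <- gru_params(2, 2)
  a <- array(rnorm(2 * 4 * 4), c(2, 4, 4))
  b <- array(rnorm(2 * 4 * 4), c(2, 4, 4))
  out <- bi_convgru(list(a, b, a), p, p)
  mid <- out[[2]]$value
  expect_equal(mid[1:2, , ], mid[3:4, , ], tolerance = 1e-12)
})
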