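# Multi-scale fusion attention: pyramid pooling bookkeeping, attention
# normalization/identity properties, and a brute-force oracle for the
# attention equations.

test_that("pyramid pooling doubles the channel count", {
  set.seed(21)
  mod <- msa_module(8)
  x <- array(rnorm(8 * 12 * 12), c(8, 12, 12))
  out <- pyramid_pool(mod, x)
  expect_identical(dim(out$value), c(16L, 12L, 12L))
})

test_that("average and maximum pools agree on spatially constant input", {
  x <- array(3.7, c(4, 12, 12))
  for (g in c(1, 2, 4, 6)) {
    expect_equal(ag_pool_avg(x, g)$value, ag_pool_max(x, g)$value)
  }
})

test_that("pyramid pooling validates grid fit and channel divisibility", {
  mod <- msa_module(8)
  expect_error(pyramid_pool(mod, array(0, c(8, 4, 4))), "too small")
  expect_error(msa_module(6), "divisible")
})

test_that("position attention is the identity at alpha = 0 and S is row-stochastic", {
  set.seed(22)
  wb <- conv_layer(3, 1, k = 1); wc <- conv_layer(3, 1, k = 1)
  wd <- conv_layer(3, 3, k = 1)
  a <- array(rnorm(3 * 4 * 4), c(3, 4, 4))
  res <- position_attention(a, wb, wc, wd, ag_param(0), return_maps = TRUE)
  expect_equal(res$out$value, a, tolerance = 1e-12)
  expect_equal(rowSums(res$S$value), rep(1, 16), tolerance = 1e-10)
})

test_that("equal similarities give the uniform two-pixel attention map", {
  # constant feature map: every projected pixel is identical, so all dot
  # products agree and each softmax row is uniform
  wb <- conv_layer(2, 1, k = 1); wc <- conv_layer(2, 1, k = 1)
  wd <- conv_layer(2, 2, k = 1)
  a <- array(1, c(2, 1, 2)) # two pixels
  res <- position_attention(a, wb, wc, wd, ag_param(0), return_maps = TRUE)
  expect_equal(res$S$value, matrix(0.5, 2, 2), tolerance = 1e-12)
})

test_that("channel attention is the identity at beta = 0 and X is row-stochastic", {
  set.seed(23)
  a <- array(rnorm(5 * 4 * 4), c(5, 4, 4))
  res <- channel_attention(a, ag_param(0), return_maps = TRUE)
  expect_equal(res$out$value, a, tolerance = 1e-12)
  expect_equal(rowSums(res$X$value), rep(1, 5), tolerance = 1e-10)
})

test_that("two identical channels produce the hand-computed attention output", {
  # with A1 = A2, X must be uniform 0.5 and E'_j = beta * A_j + A_j
  a <- array(rep(c(1, 1), each = 1), c(2, 2, 2))
  a[1, , ] <- matrix(c(0.3, -1.2, 0.5, 2.0), 2, 2)
  a[2, , ] <- a[1, , ]
  beta <- ag_param(0.7)
  res <- channel_attention(a, beta, return_maps = TRUE)
  expect_equal(res$X$value, matrix(0.5, 2, 2), tolerance = 1e-12)
  # sum_i x_ji A_i = 0.5*A + 0.5*A = A, so E' = 0.7*A + A
  expect_equal(res$out$value, 1.7 * a, tolerance = 1e-12)
})

test_that("vectorized attention matches an explicit double-loop oracle", {
  set.seed(24)
  Cc <- 3; H <- 4; W <- 4; N <- H * W
  a <- array(rnorm(Cc * H * W), c(Cc, H, W))
  wb <- conv_layer(Cc, 2, k = 1); wc <- conv_layer(Cc, 2, k = 1)
  wd <- conv_layer(Cc, Cc, k = 1)
  alpha <- ag_param(0.6); beta <- ag_param(-0.4)

  # --- oracle: scalar loops over positions and channels ---------------
  amat <- matrix(a, Cc, N)
  proj <- function(lay) {
    wv <- lay$w$value; bv <- lay$b$value
    out <- matrix(0, nrow(wv), N)
    for (j in seq_len(N)) {
      for (o in seq_len(nrow(wv))) {
        out[o, j] <- sum(wv[o, ] * amat[, j]) + bv[o]
      }
    }
    out
  }
  Bm <- proj(wb); Cm <- proj(wc); Dm <- proj(wd)
  S <- matrix(0, N, N)
  for (j in seq_len(N)) {
    e <- numeric(N)
    for (i in seq_len(N)) e[i] <- exp(sum(Bm[, i] * Cm[, j]))
    S[j, ] <- e / sum(e)
  }
  E <- matrix(0, Cc, N)
  for (j in seq_len(N)) {
    acc <- numeric(Cc)
    for (i in seq_len(N)) acc <- acc + S[j, i] * Dm[, i]
    E[, j] <- alpha$value * acc + amat[, j]
  }
  X <- matrix(0, Cc, Cc)
  for (j in seq_len(Cc)) {
    e <- numeric(Cc)
    for (i in seq_len(Cc)) e[i] <- exp(sum(amat[i, ] * amat[j, ]))
    X[j, ] <- e / sum(e)
  }
  Ep <- matrix(0, Cc, N)
  for (j in seq_len(Cc)) {
    acc <- numeric(N)
    for (i in seq_len(Cc)) acc <- acc + X[j, i] * amat[i, ]
    Ep[j, ] <- beta$value * acc + amat[j, ]
  }

  # --- vectorized implementation --------------------------------------
  pos <- position_attention(a, wb, wc, wd, alpha, return_maps = TRUE)
  chn <- channel_attention(a, beta, return_maps = TRUE)
  expect_lt(max(abs(pos$S$value - S)), 1e-6)
  expect_lt(max(abs(matrix(pos$out$value, Cc, N) - E)), 1e-6)
  expect_lt(max(abs(chn$X$value - X)), 1e-6)
  expect_lt(max(abs(matrix(chn$out$value, Cc, N) - Ep)), 1e-6)
})

test_that("row-stochasticity holds across many random maps", {
  set.seed(25)
  wb <- conv_layer(2, 1, k = 1); wc <- conv_layer(2, 1, k = 1)
  wd <- conv_layer(2, 2, k = 1)
  worst_s <- 0; worst_x <- 0
  for (i in seq_len(200)) {
    a <- array(rnorm(2 * 3 * 3, sd = runif(1, 0.5, 3)), c(2, 3, 3))
    s <- position_attention(a, wb, wc, wd, ag_param(0), return_maps = TRUE)$S$value
    x <- channel_attention(a, ag_param(0), return_maps = TRUE)$X$value
    worst_s <- max(worst_s, max(abs(rowSums(s) - 1)))
    worst_x <- max(worst_x, max(abs(rowSums(x) - 1)))
  }
  expect_lt(worst_s, 1e-5)
  expect_lt(worst_x, 1e-5)
})

test_that("channel attention is permutation-equivariant", {
  set.seed(26)
  a <- array(rnorm(4 * 3 * 3), c(4, 3, 3))
  beta <- ag_param(0.9)
  perm <- c(3, 1, 4, 2)
  out <- channel_attention(a, beta)$value
  out_p <- channel_attention(a[perm, , , drop = FALSE], beta)$value
  expect_equal(out_p, out[perm, , , drop = FALSE], tolerance = 1e-10)
})

test_that("msa_forward keeps the skip shape and is trainable", {
  set.seed(27)
  mod <- msa_module(8)
  x <- array(rnorm(8 * 12 * 12), c(8, 12, 12))
  out <- msa_forward(mod, x)
  expect_identical(dim(out$value), c(8L, 12L, 12L))
  # at alpha = beta = 0 the output equals the pooled-fused map through the
  # final projection only
  fused <- pyramid_pool(mod, x)
  expect_equal(out$value, conv_forward(mod$proj, fused)$value, tolerance = 1e-10)
  # one optimizer step moves alpha and beta away from 0
  tgt <- array(rnorm(8 * 12 * 12), c(8, 12, 12))
  params <- collect_params(mod)
  with_tape({
    l <- ag_sum(ag_powc(ag_add(msa_forward(mod, x), ag_mulc(tgt, -1)), 2))
    ag_zero_grad(params)
    ag_backward(l)
  })
  expect_gt(abs(mod$alpha$grad), 0)
  expect_gt(abs(mod$beta$grad), 0)
  sgd_step(sgd_optimizer(list(mod$alpha, mod$beta), 0), 1e-3)
  expect_true(mod$alpha$value != 0)
  expect_true(mod$beta$value != 0)
})
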