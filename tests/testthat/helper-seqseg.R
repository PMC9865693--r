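# Shared fixtures and independent oracles used across the test files.

# central finite-difference gradient check against the tape
fd_gradient <- function(make_loss, param, h = 1e-6) {
  with_tape({
    l <- make_loss()
    ag_zero_grad(list(param))
    ag_backward(l)
  })
  analytic <- param$grad
  v0 <- param$value
  numeric_g <- array(0, dim(as.array(v0)))
  for (i in seq_along(v0)) {
    param$value <- v0; param$value[i] <- v0[i] + h
    lp <- make_loss()$value
    param$value <- v0; param$value[i] <- v0[i] - h
    lm <- make_loss()$value
    numeric_g[i] <- (lp - lm) / (2 * h)
  }
  param$value <- v0
  max(abs(analytic - numeric_g))
}

# small phantom + sequence fixture shared by network-level tests
tiny_sequences <- function(seed = 7, n_slices = 8, size = 32, seq_len = 4) {
  vol <- generate_phantom(phantom_config(n_slices = n_slices, height = size,
                                         width = size, seed = seed))
  make_sequences(split_and_filter(vol), seq_len)
}

tiny_network <- function(seed = 11, seq_len = 4) {
  build_network(network_config(reduce = 16L, seq_len = seq_len, seed = seed))
}

# independent textbook dense GRU (scalars), used as the recurrence oracle
dense_gru_scalar <- function(x_seq, wz, uz, bz, wr, ur, br, wc, uc, bc) {
  h <- 0
  out <- numeric(length(x_seq))
  for (t in seq_along(x_seq)) {
    z <- 1 / (1 + exp(-(wz * x_seq[t] + uz * h + bz)))
    r <- 1 / (1 + exp(-(wr * x_seq[t] + ur * h + br)))
    hc <- tanh(wc * x_seq[t] + uc * (r * h) + bc)
    h <- (1 - z) * h + z * hc
    out[t] <- h
  }
  out
}

# connected-components labelling by breadth-first search (4-connectivity);
# independent of any package code
count_components <- function(mask) {
  m <- mask != 0
  H <- nrow(m); W <- ncol(m)
  seen <- matrix(FALSE, H, W)
  ncomp <- 0L
  for (start in which(m & !seen)) {
    if (seen[start]) next
    ncomp <- ncomp + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue) > 0) {
      p <- queue[1]; queue <- queue[-1]
      r <- (p - 1) %% H + 1; cc <- (p - 1) %/% H + 1
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- r + d[1]; cw <- cc + d[2]
        if (rr >= 1 && rr <= H && cw >= 1 && cw <= W) {
          q <- (cw - 1) * H + rr
          if (m[q] && !seen[q]) { seen[q] <- TRUE; queue <- c(queue, q) }
        }
      }
    }
  }
  ncomp
}

# brute-force Hausdorff: explicit double loop over all point pairs
hausdorff_bruteforce <- function(pred, ref, spacing = NULL) {
  d <- dim(pred)
  A <- arrayInd(which(pred != 0), d)
  B <- arrayInd(which(ref != 0), d)
  if (!is.null(spacing)) {
    A <- sweep(A, 2, spacing, "*"); B <- sweep(B, 2, spacing, "*")
  }
  directed <- function(P, Q) {
    worst <- 0
    for (i in seq_len(nrow(P))) {
      best <- Inf
      for (j in seq_len(nrow(Q))) {
        best <- min(best, sqrt(sum((P[i, ] - Q[j, ])^2)))
      }
      worst <- max(worst, best)
    }
    worst
  }
  max(directed(A, B), directed(B, A))
}

random_binary_mask <- function(H, W, p = 0.2, min_fg = 1) {
  repeat {
    m <- matrix(stats::rbinom(H * W, 1, p), H, W)
    if (sum(m) >= min_fg) return(m)
  }
}
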