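# Independent brute-force oracles used across the suite.  These stay
# deliberately naive (explicit loops) so they share no code with the
# implementation paths they check.

# direct quadruple-loop 2D convolution, stride s, valid positioning
oracle_conv2d <- function(x, w, b, s) {
  d <- dim(x); wd <- dim(w)
  ho <- (d[1] - wd[1]) %/% s + 1L
  wo <- (d[2] - wd[2]) %/% s + 1L
  y <- array(0, c(ho, wo, wd[4], d[4]))
  for (n in seq_len(d[4])) for (k in seq_len(wd[4])) {
    for (i in seq_len(ho)) for (j in seq_len(wo)) {
      acc <- b[k]
      for (c in seq_len(d[3])) for (a in seq_len(wd[1])) for (bb in seq_len(wd[2])) {
        acc <- acc + x[(i - 1) * s + a, (j - 1) * s + bb, c, n] * w[a, bb, c, k]
      }
      y[i, j, k, n] <- acc
    }
  }
  y
}

# central finite-difference gradient of scalar f at p
oracle_fd_grad <- function(f, p, eps = 1e-6) {
  g <- p
  for (i in seq_along(p)) {
    ph <- p; ph[i] <- ph[i] + eps
    pl <- p; pl[i] <- pl[i] - eps
    g[i] <- (f(ph) - f(pl)) / (2 * eps)
  }
  g
}

# windowed SSIM by explicit double loop over window positions
oracle_ssim <- function(x, y, c1, c2, k) {
  vals <- c()
  for (i in seq_len(nrow(x) - k + 1)) {
    for (j in seq_len(ncol(x) - k + 1)) {
      wx <- as.vector(x[i:(i + k - 1), j:(j + k - 1)])
      wy <- as.vector(y[i:(i + k - 1), j:(j + k - 1)])
      mx <- mean(wx); my <- mean(wy)
      vx <- mean((wx - mx)^2); vy <- mean((wy - my)^2)
      cxy <- mean((wx - mx) * (wy - my))
      vals <- c(vals, ((2 * mx * my + c1) * (2 * cxy + c2)) /
                  ((mx^2 + my^2 + c1) * (vx + vy + c2)))
    }
  }
  mean(vals)
}

# per-voxel loop metrics
oracle_me <- function(ct, sct, mask) {
  s <- 0; n <- 0
  for (i in seq_along(ct)) {
    if (mask[i] == 1) { s <- s + (ct[i] - sct[i]); n <- n + 1 }
  }
  s / n
}
oracle_mae <- function(ct, sct, mask) {
  s <- 0; n <- 0
  for (i in seq_along(ct)) {
    if (mask[i] == 1) { s <- s + abs(ct[i] - sct[i]); n <- n + 1 }
  }
  s / n
}
oracle_mse <- function(ct, sct, mask) {
  s <- 0; n <- 0
  for (i in seq_along(ct)) {
    if (mask[i] == 1) { s <- s + (ct[i] - sct[i])^2; n <- n + 1 }
  }
  s / n
}

# sort-based percentile (linear interpolation between order statistics)
oracle_percentile <- function(x, p) {
  xs <- sort(x)
  h <- (length(xs) - 1) * p + 1
  lo <- floor(h)
  xs[lo] + (h - lo) * (xs[min(lo + 1, length(xs))] - xs[lo])
}

# smooth random texture for flow tests
make_texture <- function(n, seed, sigma = 1.5) {
  set.seed(seed)
  z <- matrix(rnorm(n * n), n)
  k <- exp(-(-5:5)^2 / (2 * sigma^2)); k <- k / sum(k)
  km <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- pmin(pmax(i + (-5:5), 1), n)
    for (j in seq_along(idx)) km[i, idx[j]] <- km[i, idx[j]] + k[j]
  }
  km %*% z %*% t(km)
}
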