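## Separable image resampling built from explicit weight matrices:
## a resize is  W_rows %*% img %*% t(W_cols),  which keeps the kernels
## inspectable and makes constant images provably invariant (each row of a
## weight matrix sums to 1).

# Keys bicubic kernel, a = -0.5 (the common "bicubic" convention)
cubic_kernel <- function(t, a = -0.5) {
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

# n_out x n_in dense interpolation matrix; source coordinates follow the
# half-pixel-centre convention src = (dst + 0.5) * n_in/n_out - 0.5.
resize_matrix <- function(n_in, n_out, method = c("cubic", "linear", "nearest")) {
  method <- match.arg(method)
  m <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (j in seq_len(n_out)) {
    src <- (j - 0.5) * scale - 0.5 # 0-based
    if (method == "nearest") {
      idx <- min(max(floor(src + 0.5), 0), n_in - 1)
      m[j, idx + 1] <- 1
    } else {
      if (method == "cubic") {
        taps <- floor(src) + (-1:2)
        w <- cubic_kernel(src - taps)
      } else {
        taps <- floor(src) + (0:1)
        w <- c(1 - (src - taps[1]), src - taps[1])
      }
      w <- w / sum(w)
      taps <- pmin(pmax(taps, 0), n_in - 1)
      for (k in seq_along(taps)) m[j, taps[k] + 1] <- m[j, taps[k] + 1] + w[k]
    }
  }
  m
}

resize_slice <- function(img, out_h, out_w, method = "cubic") {
  wr <- resize_matrix(nrow(img), out_h, method)
  wc <- resize_matrix(ncol(img), out_w, method)
  wr %*% img %*% t(wc)
}

# n x n correlation matrix along one axis with replicated borders:
# (M f)[i] = sum_j k[j] f(clamp(i + j - h - 1))
conv_matrix <- function(n, k) {
  h <- (length(k) - 1L) %/% 2L
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- pmin(pmax(i + seq_along(k) - h - 1L, 1L), n)
    for (j in seq_along(k)) m[i, idx[j]] <- m[i, idx[j]] + k[j]
  }
  m
}

gaussian_kernel <- function(sigma, half = ceiling(3 * sigma)) {
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# separable filtering with replicate borders
sep_filter <- function(img, k_row, k_col = k_row) {
  conv_matrix(nrow(img), k_row) %*% img %*% t(conv_matrix(ncol(img), k_col))
}
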