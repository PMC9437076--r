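## Windowed structural similarity (SSIM) with a uniform kernel.
##
## Statistics (means, variances, covariance) are taken over every valid
## 11x11 window position via integral images; the index is the mean of the
## per-window map.  An analytic gradient with respect to the first image is
## provided for use as a training loss.  Inputs are expected on a common
## [0, 1] intensity scale.

#' SSIM stabilization constants and window size
#'
#' Defaults follow the model configuration this package implements:
#' `C1 = 0.0001` and `C2 = 0.009` on a `[0, 1]` intensity scale, windows of
#' size 11x11.  Note `C2 = 0.009` differs from the conventional
#' `(0.03)^2 = 0.0009`; pass `c2 = 0.0009` to use the conventional value.
#'
#' @param c1,c2 positive stabilization constants.
#' @param window odd window side length (scalar) or a length-2 vector whose
#'   entries must be equal (windows are square).
#' @return list of class `ssim_constants`.
#' @export
ssim_constants <- function(c1 = 0.0001, c2 = 0.009, window = 11L) {
  if (length(window) == 2L) {
    stopifnot(window[1] == window[2])
    window <- window[1]
  }
  window <- as.integer(window)
  stopifnot(c1 > 0, c2 > 0, window %% 2L == 1L, window >= 3L)
  structure(list(c1 = c1, c2 = c2, window = window), class = "ssim_constants")
}

# sums over all k x k valid windows via an integral image; the row-wise
# cumulative sum is a triangular matmul so both passes stay vectorized
box_sum <- function(m, k) {
  d <- dim(m)
  lo <- matrix(0, d[1], d[1])
  lo[lower.tri(lo, diag = TRUE)] <- 1
  up <- matrix(0, d[2], d[2])
  up[upper.tri(up, diag = TRUE)] <- 1
  ii <- matrix(0, d[1] + 1L, d[2] + 1L)
  ii[-1L, -1L] <- lo %*% m %*% up
  hi <- seq(k + 1L, d[1] + 1L)
  lo <- seq_len(d[1] - k + 1L)
  wh <- seq(k + 1L, d[2] + 1L)
  wl <- seq_len(d[2] - k + 1L)
  ii[hi, wh] - ii[lo, wh] - ii[hi, wl] + ii[lo, wl]
}

# adjoint of the valid-window mean: scatter per-window coefficients back
# over the pixels each window covers
box_spread <- function(cmap, k, out_dim) {
  z <- matrix(0, out_dim[1] + k - 1L, out_dim[2] + k - 1L)
  z[(k - 1L) + seq_len(nrow(cmap)), (k - 1L) + seq_len(ncol(cmap))] <- cmap
  box_sum(z, k)
}

ssim_window_stats <- function(x, y, c) {
  k <- c$window
  M <- k * k
  mx <- box_sum(x, k) / M
  my <- box_sum(y, k) / M
  vx <- box_sum(x * x, k) / M - mx * mx
  vy <- box_sum(y * y, k) / M - my * my
  cxy <- box_sum(x * y, k) / M - mx * my
  a1 <- 2 * mx * my + c$c1
  a2 <- 2 * cxy + c$c2
  b1 <- mx * mx + my * my + c$c1
  b2 <- vx + vy + c$c2
  list(mx = mx, my = my, a1 = a1, a2 = a2, b1 = b1, b2 = b2,
       s = (a1 * a2) / (b1 * b2), M = M, k = k)
}

#' Windowed SSIM index between two images
#'
#' Computes the local SSIM over every valid `window x window` position
#' (uniform window statistics, no padding) and returns the mean across
#' positions.  Both images should share a common normalized intensity scale,
#' typically `[0, 1]`.
#'
#' @param x,y numeric matrices of equal size, at least as large as the window.
#' @param c an [ssim_constants()] object.
#' @return scalar in `[-1, 1]`.
#' @export
ssim_index <- function(x, y, c = ssim_constants()) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!identical(dim(x), dim(y))) {
    stop("ssim_index: images must share one shape", call. = FALSE)
  }
  if (any(dim(x) < c$window)) {
    stop("ssim_index: image smaller than the SSIM window", call. = FALSE)
  }
  mean(ssim_window_stats(x, y, c)$s)
}

# d mean-SSIM / dx as an H x W matrix; used by the training loss.
# For each window: d SSIM/d x_i =
#   (2 / (M B1 B2)) [ mu_y A2 + A1 (y_i - mu_y) - S (mu_x B2 + B1 (x_i - mu_x)) ]
# which splits into a constant, a y_i-proportional and an x_i-proportional
# per-window coefficient, each scattered back over its window.
ssim_index_grad <- function(x, y, c = ssim_constants()) {
  x <- as.matrix(x); y <- as.matrix(y)
  st <- ssim_window_stats(x, y, c)
  P <- length(st$s)
  alpha <- 2 / (st$M * st$b1 * st$b2 * P)
  c_const <- alpha * (st$my * (st$a2 - st$a1) + st$s * st$mx * (st$b1 - st$b2))
  c_y <- alpha * st$a1
  c_x <- -alpha * st$s * st$b1
  k <- st$k
  box_spread(c_const, k, dim(x)) +
    y * box_spread(c_y, k, dim(x)) +
    x * box_spread(c_x, k, dim(x))
}
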