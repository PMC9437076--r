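## Minimal convolutional-network engine with hand-derived backpropagation.
##
## Activations are numeric arrays of dim (H, W, C, N); convolutions run
## through the compiled im2col kernels in src/conv.cpp.  Every layer is a
## plain list with a `type`, optional `params`, and static configuration;
## `nn_forward()` caches what `nn_backward()` needs.  This keeps the whole
## training loop deterministic and introspectable, which the tests rely on.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so seeded constructors
#' (networks, phantoms) do not perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

as_nchw <- function(x) {
  # promote (H,W) or (H,W,C) to (H,W,C,N)
  d <- dim(x)
  if (is.null(d)) stop("expected an array", call. = FALSE)
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

## ---- padding -----------------------------------------------------------

pad_indices_reflect <- function(n, p) {
  # torch-style reflection (edge not repeated): for n=4, p=2 -> 3 2 1 2 3 4 3 2
  if (p >= n) stop("reflection pad wider than input", call. = FALSE)
  idx <- c(seq(p + 1L, 2L, by = -1L), seq_len(n), seq(n - 1L, n - p, by = -1L))
  idx[seq_len(2L * p + n)]
}

pad2d <- function(x, p, mode = c("zero", "reflect")) {
  mode <- match.arg(mode)
  if (p == 0L) return(x)
  d <- dim(x)
  if (mode == "zero") {
    out <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4]))
    out[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
    out
  } else {
    ih <- pad_indices_reflect(d[1], p)
    iw <- pad_indices_reflect(d[2], p)
    x[ih, iw, , , drop = FALSE]
  }
}

unpad2d_grad <- function(dp, p, mode, orig_hw) {
  # adjoint of pad2d: fold padded-gradient rows/cols back onto sources
  if (p == 0L) return(dp)
  h <- orig_hw[1]; w <- orig_hw[2]
  if (mode == "zero") {
    return(dp[p + seq_len(h), p + seq_len(w), , , drop = FALSE])
  }
  # reflection (edge not repeated): padded row r <= p reflects to source
  # row p+2-r, padded row p+h+r to source row h-r; rows first (over all
  # padded columns, so corners fold through both stages), then columns
  tmp <- dp[p + seq_len(h), , , , drop = FALSE]
  for (r in seq_len(p)) {
    tmp[p + 2L - r, , , ] <- tmp[p + 2L - r, , , ] + dp[r, , , ]
    tmp[h - r, , , ] <- tmp[h - r, , , ] + dp[p + h + r, , , ]
  }
  core <- tmp[, p + seq_len(w), , , drop = FALSE]
  for (cc in seq_len(p)) {
    core[, p + 2L - cc, , ] <- core[, p + 2L - cc, , ] + tmp[, cc, , ]
    core[, w - cc, , ] <- core[, w - cc, , ] + tmp[, p + w + cc, , ]
  }
  core
}

## ---- layer constructors ------------------------------------------------

layer_conv <- function(in_ch, out_ch, k, stride = 1L, pad = 0L,
                       pad_mode = "zero", init_sd = 0.02) {
  list(type = "conv", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad), pad_mode = pad_mode,
       params = list(
         w = array(stats::rnorm(k * k * in_ch * out_ch, 0, init_sd),
                   c(k, k, in_ch, out_ch)),
         b = numeric(out_ch)))
}

layer_instnorm <- function(eps = 1e-5) list(type = "instnorm", eps = eps)
layer_relu <- function() list(type = "relu")
layer_lrelu <- function(slope = 0.2) list(type = "lrelu", slope = slope)
layer_tanh <- function() list(type = "tanh")
layer_sigmoid <- function() list(type = "sigmoid")
layer_upsample2 <- function() list(type = "upsample2")
layer_gap <- function() list(type = "gap")

layer_resblock <- function(ch, init_sd = 0.02) {
  list(type = "resblock",
       layers = list(
         layer_conv(ch, ch, 3L, 1L, 1L, "reflect", init_sd),
         layer_instnorm(),
         layer_relu(),
         layer_conv(ch, ch, 3L, 1L, 1L, "reflect", init_sd),
         layer_instnorm()))
}

## ---- forward / backward ------------------------------------------------

instnorm_stats <- function(x, eps) {
  d <- dim(x)
  np <- d[1] * d[2]
  m <- matrix(x, np, d[3] * d[4])
  mu <- colMeans(m)
  xc <- m - rep(mu, each = np)
  s <- sqrt(colMeans(xc * xc) + eps)
  xn <- xc / rep(s, each = np)
  list(xn = xn, s = s, d = d)
}

layer_forward <- function(layer, x) {
  switch(layer$type,
    conv = {
      xp <- pad2d(x, layer$pad, layer$pad_mode)
      y <- cpp_conv2d_forward(xp, layer$params$w, layer$params$b, layer$stride)
      list(y = y, cache = list(xp = xp, hw = dim(x)[1:2]))
    },
    instnorm = {
      st <- instnorm_stats(x, layer$eps)
      y <- array(st$xn, st$d)
      list(y = y, cache = st)
    },
    relu = {
      pos <- x > 0
      list(y = x * pos, cache = pos)
    },
    lrelu = {
      pos <- x > 0
      list(y = x * (layer$slope + (1 - layer$slope) * pos), cache = pos)
    },
    tanh = {
      y <- tanh(x)
      list(y = y, cache = y)
    },
    sigmoid = {
      y <- 1 / (1 + exp(-x))
      list(y = y, cache = y)
    },
    upsample2 = {
      d <- dim(x)
      y <- x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
             drop = FALSE]
      list(y = y, cache = d)
    },
    gap = {
      d <- dim(x)
      y <- colMeans(matrix(x, d[1] * d[2] * d[3], d[4]))
      list(y = y, cache = d)
    },
    resblock = {
      h <- x
      caches <- vector("list", length(layer$layers))
      for (i in seq_along(layer$layers)) {
        fw <- layer_forward(layer$layers[[i]], h)
        h <- fw$y
        caches[[i]] <- fw$cache
      }
      list(y = x + h, cache = caches)
    },
    stop("unknown layer type: ", layer$type)
  )
}

layer_backward <- function(layer, cache, dy, need_dx = TRUE,
                           need_grads = TRUE) {
  switch(layer$type,
    conv = {
      bw <- cpp_conv2d_backward(cache$xp, layer$params$w, dy, layer$stride,
                                need_dx, need_grads)
      dx <- if (need_dx) {
        unpad2d_grad(bw$dx, layer$pad, layer$pad_mode, cache$hw)
      }
      list(dx = dx,
           grads = if (need_grads) list(w = bw$dw, b = bw$db))
    },
    instnorm = {
      d <- cache$d
      np <- d[1] * d[2]
      g <- matrix(dy, np, d[3] * d[4])
      gm <- colMeans(g)
      gxn <- colMeans(g * cache$xn)
      dx <- (g - rep(gm, each = np) - cache$xn * rep(gxn, each = np)) /
        rep(cache$s, each = np)
      list(dx = array(dx, d), grads = NULL)
    },
    relu = list(dx = dy * cache, grads = NULL),
    lrelu = list(dx = dy * (layer$slope + (1 - layer$slope) * cache),
                 grads = NULL),
    tanh = list(dx = dy * (1 - cache^2), grads = NULL),
    sigmoid = list(dx = dy * cache * (1 - cache), grads = NULL),
    upsample2 = {
      d <- cache
      oh <- seq(1L, 2L * d[1], by = 2L)
      ow <- seq(1L, 2L * d[2], by = 2L)
      dx <- dy[oh, ow, , , drop = FALSE] + dy[oh + 1L, ow, , , drop = FALSE] +
        dy[oh, ow + 1L, , , drop = FALSE] + dy[oh + 1L, ow + 1L, , , drop = FALSE]
      list(dx = dx, grads = NULL)
    },
    gap = {
      d <- cache
      per <- dy / (d[1] * d[2] * d[3])
      dx <- array(rep(per, each = d[1] * d[2] * d[3]), d)
      list(dx = dx, grads = NULL)
    },
    resblock = {
      dh <- dy
      grads <- vector("list", length(layer$layers))
      for (i in rev(seq_along(layer$layers))) {
        bw <- layer_backward(layer$layers[[i]], cache[[i]], dh,
                             need_dx = TRUE, need_grads = need_grads)
        dh <- bw$dx
        grads[i] <- list(bw$grads) # [i]<-list(): keep NULL slots
      }
      list(dx = dy + dh, grads = grads)
    },
    stop("unknown layer type: ", layer$type)
  )
}

nn_forward <- function(net, x) {
  x <- as_nchw(x)
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    fw <- layer_forward(net$layers[[i]], x)
    x <- fw$y
    caches[[i]] <- fw$cache
  }
  list(y = x, caches = caches)
}

# need_dx: propagate the input gradient past layer 1 (only needed when the
# input is itself a network output, e.g. the cycle reconstruction pass);
# need_grads: accumulate parameter gradients (FALSE when backpropagating an
# adversarial term through a frozen discriminator).
nn_backward <- function(net, caches, dy, need_dx = TRUE, need_grads = TRUE) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    bw <- layer_backward(net$layers[[i]], caches[[i]], dy,
                         need_dx = need_dx || i > 1L,
                         need_grads = need_grads)
    dy <- bw$dx
    grads[i] <- list(bw$grads) # [i]<-list(): keep NULL slots
  }
  list(dx = dy, grads = grads)
}

#' @keywords internal
nn_predict <- function(net, x) nn_forward(net, x)$y

## ---- parameter bookkeeping ---------------------------------------------

grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  for (i in seq_along(a)) {
    # `a[i] <- list(...)`: assigning with [[<- would drop NULL slots and
    # shift the layer alignment
    if (is.null(a[[i]])) {
      a[i] <- list(b[[i]])
    } else if (is.list(a[[i]])) {
      a[i] <- list(grads_add(a[[i]], b[[i]]))
    } else {
      a[[i]] <- a[[i]] + b[[i]]
    }
  }
  a
}
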