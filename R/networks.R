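## Generator and discriminator architectures.
##
## Both generators (MR -> sCT and CT -> sMR) share a residual
## encoder-decoder: a 7x7 reflection-padded stem, two stride-2
## downsamplings, a stack of residual blocks at 4x the base width, two
## nearest-neighbour upsamplings each followed by a 3x3 convolution, and a
## 7x7 head with tanh output.  The discriminators are 5-block patch
## networks (4x4 kernels, stride 2, channel width doubling 64->512,
## instance norm + leaky ReLU slope 0.2) whose sigmoid head is spatially
## averaged to one score per image in [0, 1].
##
## Networks consume and emit values on the [-1, 1] scale; `to_net()` /
## `from_net()` convert from/to the 16-bit data scale.

#' Generator specification
#'
#' @param role `"G_CT"` (MR to synthetic CT) or `"G_MR"` (CT to synthetic MR).
#' @param ngf base channel width of the first convolution. The reference
#'   architecture uses 64; tests and desk-scale runs use narrower nets.
#' @param n_res number of residual blocks (9 in the reference architecture).
#' @return a list of class `generator_spec`.
#' @export
generator_spec <- function(role = c("G_CT", "G_MR"), ngf = 64L, n_res = 9L) {
  role <- match.arg(role)
  stopifnot(ngf >= 1L, n_res >= 1L)
  structure(list(role = role, ngf = as.integer(ngf), n_res = as.integer(n_res),
                 in_ch = 1L, out_ch = 1L),
            class = "generator_spec")
}

#' Discriminator specification
#'
#' @param ndf channel count of the first block (64 in the reference
#'   architecture; blocks 2-4 double it).
#' @param patch_output if `TRUE` the raw decision map is returned without
#'   spatial averaging (off by default; the default head yields one scalar
#'   per image).
#' @return a list of class `discriminator_spec`.
#' @export
discriminator_spec <- function(ndf = 64L, patch_output = FALSE) {
  structure(list(ndf = as.integer(ndf), leaky_slope = 0.2,
                 patch_output = isTRUE(patch_output)),
            class = "discriminator_spec")
}

#' Build a residual translation generator
#'
#' Weights are zero-mean Gaussian (sd 0.02), biases zero; construction is
#' deterministic under `seed` and does not disturb the caller's RNG state.
#'
#' @param spec a [generator_spec()].
#' @param seed integer seed for weight initialization.
#' @return a network object (list with `layers`, `spec`).
#' @export
build_generator <- function(spec = generator_spec(), seed = 1L) {
  stopifnot(inherits(spec, "generator_spec"))
  ngf <- spec$ngf
  with_seed(seed, {
    layers <- c(
      list(
        layer_conv(spec$in_ch, ngf, 7L, 1L, 3L, "reflect"),
        layer_instnorm(), layer_relu(),
        layer_conv(ngf, ngf * 2L, 3L, 2L, 1L, "zero"),
        layer_instnorm(), layer_relu(),
        layer_conv(ngf * 2L, ngf * 4L, 3L, 2L, 1L, "zero"),
        layer_instnorm(), layer_relu()
      ),
      lapply(seq_len(spec$n_res), function(i) layer_resblock(ngf * 4L)),
      list(
        layer_upsample2(),
        layer_conv(ngf * 4L, ngf * 2L, 3L, 1L, 1L, "zero"),
        layer_instnorm(), layer_relu(),
        layer_upsample2(),
        layer_conv(ngf * 2L, ngf, 3L, 1L, 1L, "zero"),
        layer_instnorm(), layer_relu(),
        layer_conv(ngf, spec$out_ch, 7L, 1L, 3L, "reflect"),
        layer_tanh()
      )
    )
    structure(list(layers = layers, spec = spec, kind = "generator"),
              class = "sctflow_net")
  })
}

#' Build a patch discriminator
#'
#' Five convolutional blocks with 4x4 kernels: blocks 1-4 use stride 2 and
#' double the channel width from `ndf`, each followed by instance
#' normalization and leaky ReLU (slope 0.2); the final block maps to a
#' 1-channel sigmoid decision map which is averaged to a scalar per image
#' unless `spec$patch_output` is set.
#'
#' @param spec a [discriminator_spec()].
#' @param seed integer seed for weight initialization.
#' @return a network object.
#' @export
build_discriminator <- function(spec = discriminator_spec(), seed = 1L) {
  stopifnot(inherits(spec, "discriminator_spec"))
  ndf <- spec$ndf
  with_seed(seed, {
    layers <- list(
      layer_conv(1L, ndf, 4L, 2L, 1L, "zero"),
      layer_instnorm(), layer_lrelu(spec$leaky_slope),
      layer_conv(ndf, ndf * 2L, 4L, 2L, 1L, "zero"),
      layer_instnorm(), layer_lrelu(spec$leaky_slope),
      layer_conv(ndf * 2L, ndf * 4L, 4L, 2L, 1L, "zero"),
      layer_instnorm(), layer_lrelu(spec$leaky_slope),
      layer_conv(ndf * 4L, ndf * 8L, 4L, 2L, 1L, "zero"),
      layer_instnorm(), layer_lrelu(spec$leaky_slope),
      layer_conv(ndf * 8L, 1L, 4L, 1L, 1L, "zero"),
      layer_sigmoid()
    )
    if (!spec$patch_output) layers <- c(layers, list(layer_gap()))
    structure(list(layers = layers, spec = spec, kind = "discriminator"),
              class = "sctflow_net")
  })
}

#' Rescale 16-bit intensities to the network range
#'
#' @param x array of values in `[0, 65535]`.
#' @return array in `[-1, 1]`.
#' @export
to_net <- function(x) x / 65535 * 2 - 1

#' Rescale network-range intensities back to the 16-bit scale
#'
#' @param x array of values in `[-1, 1]`.
#' @return array in `[0, 65535]`.
#' @export
from_net <- function(x) (x + 1) / 2 * 65535

#' Run a generator on a stack of 16-bit slices
#'
#' Convenience inference wrapper: converts to the network range, applies the
#' generator, converts back and clips to `[0, 65535]`.
#'
#' @param net a generator built by [build_generator()].
#' @param slices array (H, W) or (H, W, Z) of values in `[0, 65535]`.
#' @return array of synthesized slices, same shape, in `[0, 65535]`.
#' @export
translate_slices <- function(net, slices) {
  d <- dim(slices)
  x <- as_nchw(to_net(slices))
  if (dim(x)[3] > 1L) { # (H,W,Z) arrived as channels; move Z to batch
    x <- array(x, c(dim(x)[1], dim(x)[2], 1L, dim(x)[3] * dim(x)[4]))
  }
  y <- nn_predict(net, x)
  out <- pmin(pmax(from_net(y), 0), 65535)
  array(out, d)
}

count_resblocks <- function(net) {
  sum(vapply(net$layers, function(l) identical(l$type, "resblock"), logical(1)))
}

conv_out_channels <- function(net) {
  chans <- vapply(net$layers, function(l) {
    if (identical(l$type, "conv")) dim(l$params$w)[4] else NA_integer_
  }, integer(1))
  chans[!is.na(chans)]
}

## ---- Adam ---------------------------------------------------------------

# Optimizer state mirrors the layer/params nesting: for each parameterised
# layer, list(m = ..., v = ...) per parameter array.

adam_init <- function(layers) {
  lapply(layers, function(ly) {
    if (ly$type == "resblock") return(adam_init(ly$layers))
    if (is.null(ly$params)) return(NULL)
    lapply(ly$params, function(p) list(m = p * 0, v = p * 0))
  })
}

adam_update_layers <- function(layers, grads, state, lr, beta1, beta2, eps, t) {
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "resblock") {
      up <- adam_update_layers(ly$layers, grads[[i]], state[[i]],
                               lr, beta1, beta2, eps, t)
      layers[[i]]$layers <- up$layers
      state[[i]] <- up$state
    } else if (!is.null(ly$params) && !is.null(grads[[i]])) {
      for (pn in names(ly$params)) {
        g <- grads[[i]][[pn]]
        st <- state[[i]][[pn]]
        st$m <- beta1 * st$m + (1 - beta1) * g
        st$v <- beta2 * st$v + (1 - beta2) * g * g
        mhat <- st$m / (1 - beta1^t)
        vhat <- st$v / (1 - beta2^t)
        layers[[i]]$params[[pn]] <- ly$params[[pn]] - lr * mhat / (sqrt(vhat) + eps)
        state[[i]][[pn]] <- st
      }
    }
  }
  list(layers = layers, state = state)
}

#' @keywords internal
adam_step <- function(net, grads, opt, lr) {
  opt$t <- opt$t + 1L
  up <- adam_update_layers(net$layers, grads, opt$state, lr,
                           opt$beta1, opt$beta2, opt$eps, opt$t)
  net$layers <- up$layers
  opt$state <- up$state
  list(net = net, opt = opt)
}

#' @keywords internal
adam_new <- function(net, beta1 = 0.5, beta2 = 0.999, eps = 1e-8) {
  list(state = adam_init(net$layers), t = 0L,
       beta1 = beta1, beta2 = beta2, eps = eps)
}
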