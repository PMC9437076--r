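## Dense optical flow between adjacent axial slices.
##
## The estimator follows Farneback's polynomial-expansion method: each image
## is locally approximated as a quadratic polynomial under a Gaussian
## applicability window, and the displacement field is solved from the
## expansion coefficients with windowed averaging, iterated over a coarse-
## to-fine pyramid.  Flows are estimated on ground-truth slices only and
## cached in advance of training.
##
## Direction semantics: `farneback_flow(a, b)` returns the motion field from
## `a` to `b`, i.e. the field `d` with `a(p) ~ b(p + d(p))`, so backward-
## sampling `b` through the field reconstructs `a`:  `warp(b, d) ~ a`.
## The cached field `f[n, k]` is therefore estimated as
## `farneback_flow(slice_k, slice_n)`, making `warp(slice_n, f[n, k])`
## approximate `slice_k`.

#' Construct a flow field
#'
#' @param displacements H x W x 2 array of per-pixel displacements in pixel
#'   units, component 1 = row offset, component 2 = column offset.
#' @param direction `"to_prev"` or `"to_next"` relative to the source slice.
#' @param source_index index of the slice the field is applied to.
#' @return object of class `flow_field`.
#' @export
flow_field <- function(displacements, direction = c("to_prev", "to_next"),
                       source_index = NA_integer_) {
  direction <- match.arg(direction)
  d <- dim(displacements)
  if (length(d) != 3L || d[3] != 2L) {
    stop("flow_field: displacements must be H x W x 2", call. = FALSE)
  }
  if (!all(is.finite(displacements))) {
    stop("flow_field: non-finite displacements", call. = FALSE)
  }
  structure(list(displacements = displacements, direction = direction,
                 source_index = as.integer(source_index)),
            class = "flow_field")
}

#' Farneback flow estimation parameters
#'
#' Defaults: pyramid scale 0.5, 3 levels, averaging window 15, 3 iterations
#' per level, polynomial-expansion half-width 5 with Gaussian applicability
#' sigma 1.1.  Images are linearly rescaled (jointly, per pair) to `[0, 255]`
#' before estimation.
#'
#' @param pyr_scale pyramid downscale factor in (0, 1).
#' @param levels number of pyramid levels.
#' @param winsize side of the box window used to average the local systems.
#' @param iterations displacement-refinement iterations per level.
#' @param poly_n half-width of the polynomial-expansion window.
#' @param poly_sigma Gaussian applicability sigma.
#' @return list of class `flow_params`.
#' @export
flow_params <- function(pyr_scale = 0.5, levels = 3L, winsize = 15L,
                        iterations = 3L, poly_n = 5L, poly_sigma = 1.1) {
  stopifnot(pyr_scale > 0, pyr_scale < 1, levels >= 1L, winsize >= 3L,
            iterations >= 1L, poly_n >= 2L, poly_sigma > 0)
  structure(list(pyr_scale = pyr_scale, levels = as.integer(levels),
                 winsize = as.integer(winsize),
                 iterations = as.integer(iterations),
                 poly_n = as.integer(poly_n), poly_sigma = poly_sigma),
            class = "flow_params")
}

## ---- warping ------------------------------------------------------------

#' Warp an image through a flow field
#'
#' Backward sampling: `out(p) = img(p + flow(p))` with bilinear interpolation;
#' sample coordinates are clamped to the image (border replication).  Zero
#' flow reproduces the input bit-exactly.
#'
#' @param img numeric matrix.
#' @param flow a [flow_field()] or an H x W x 2 displacement array.
#' @return warped matrix, same shape as `img`.
#' @export
warp <- function(img, flow) {
  fl <- if (inherits(flow, "flow_field")) flow$displacements else flow
  if (!all(is.finite(fl))) stop("warp: non-finite flow", call. = FALSE)
  h <- nrow(img); w <- ncol(img)
  if (!identical(dim(fl)[1:2], c(h, w))) {
    stop("warp: flow shape does not match image", call. = FALSE)
  }
  r <- pmin(pmax(row(img) + fl[, , 1L], 1), h)
  cc <- pmin(pmax(col(img) + fl[, , 2L], 1), w)
  r0 <- floor(r); c0 <- floor(cc)
  r1 <- pmin(r0 + 1, h); c1 <- pmin(c0 + 1, w)
  wr <- r - r0; wc <- cc - c0
  i00 <- (c0 - 1) * h + r0
  i10 <- (c0 - 1) * h + r1
  i01 <- (c1 - 1) * h + r0
  i11 <- (c1 - 1) * h + r1
  out <- (1 - wr) * (1 - wc) * img[i00] + wr * (1 - wc) * img[i10] +
    (1 - wr) * wc * img[i01] + wr * wc * img[i11]
  dim(out) <- c(h, w)
  out
}

# vector-Jacobian product of warp with respect to the sampled image:
# scatter each output gradient onto its four bilinear source pixels.
warp_input_grad <- function(dout, flow, img_dim) {
  fl <- if (inherits(flow, "flow_field")) flow$displacements else flow
  h <- img_dim[1]; w <- img_dim[2]
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  r <- pmin(pmax(rows + fl[, , 1L], 1), h)
  cc <- pmin(pmax(cols + fl[, , 2L], 1), w)
  r0 <- floor(r); c0 <- floor(cc)
  r1 <- pmin(r0 + 1, h); c1 <- pmin(c0 + 1, w)
  wr <- r - r0; wc <- cc - c0
  idx <- as.integer(c((c0 - 1) * h + r0, (c0 - 1) * h + r1,
                      (c1 - 1) * h + r0, (c1 - 1) * h + r1))
  val <- c((1 - wr) * (1 - wc) * dout, wr * (1 - wc) * dout,
           (1 - wr) * wc * dout, wr * wc * dout)
  matrix(cpp_scatter_add(idx, val, h * w), h, w)
}

## ---- Farneback estimation ------------------------------------------------

# Quadratic polynomial expansion f(p + u) ~ u' A u + b' u + c under a
# Gaussian applicability of half-width n.  Returns per-pixel A (3 symmetric
# components) and b (2 components); u = (y, x).
poly_expansion <- function(img, n, sigma) {
  x <- seq(-n, n)
  g <- exp(-x^2 / (2 * sigma^2)); g <- g / sum(g)
  gx <- g * x
  gx2 <- g * x^2
  ar <- list(g = conv_matrix(nrow(img), g), gx = conv_matrix(nrow(img), gx),
             gx2 = conv_matrix(nrow(img), gx2))
  ac <- list(g = t(conv_matrix(ncol(img), g)), gx = t(conv_matrix(ncol(img), gx)),
             gx2 = t(conv_matrix(ncol(img), gx2)))
  m1  <- ar$g   %*% img %*% ac$g
  mx  <- ar$g   %*% img %*% ac$gx
  my  <- ar$gx  %*% img %*% ac$g
  mxx <- ar$g   %*% img %*% ac$gx2
  myy <- ar$gx2 %*% img %*% ac$g
  mxy <- ar$gx  %*% img %*% ac$gx

  # metric G = sum w(y) w(x) phi phi' over the window, phi = (1,x,y,x2,y2,xy)
  wy <- g; wx <- g
  G <- matrix(0, 6, 6)
  for (iy in seq_along(x)) {
    for (ix in seq_along(x)) {
      phi <- c(1, x[ix], x[iy], x[ix]^2, x[iy]^2, x[ix] * x[iy])
      G <- G + wy[iy] * wx[ix] * tcrossprod(phi)
    }
  }
  m <- rbind(as.vector(m1), as.vector(mx), as.vector(my),
             as.vector(mxx), as.vector(myy), as.vector(mxy))
  co <- solve(G, m) # rows: c, cx, cy, cxx, cyy, cxy
  d <- dim(img)
  list(a11 = matrix(co[5, ], d[1], d[2]),  # y^2 coefficient
       a22 = matrix(co[4, ], d[1], d[2]),  # x^2 coefficient
       a12 = matrix(co[6, ] / 2, d[1], d[2]),
       by = matrix(co[3, ], d[1], d[2]),
       bx = matrix(co[2, ], d[1], d[2]))
}

# one displacement refinement at a single scale.  The second expansion is
# fetched at x + d(x) by bilinear sampling, so the A*d compensation below
# matches the fetch displacement exactly (a rounded fetch paired with a
# full-d compensation systematically overshoots).
flow_update <- function(p1, p2, d, winsize) {
  h <- nrow(p1$a11); w <- ncol(p1$a11)
  a11 <- (p1$a11 + warp(p2$a11, d)) / 2
  a22 <- (p1$a22 + warp(p2$a22, d)) / 2
  a12 <- (p1$a12 + warp(p2$a12, d)) / 2
  dby <- -0.5 * (warp(p2$by, d) - p1$by) +
    a11 * d[, , 1L] + a12 * d[, , 2L]
  dbx <- -0.5 * (warp(p2$bx, d) - p1$bx) +
    a12 * d[, , 1L] + a22 * d[, , 2L]

  g11 <- a11 * a11 + a12 * a12
  g12 <- a12 * (a11 + a22)
  g22 <- a22 * a22 + a12 * a12
  hy <- a11 * dby + a12 * dbx
  hx <- a12 * dby + a22 * dbx

  k <- rep(1 / winsize, winsize)
  g11 <- sep_filter(g11, k); g12 <- sep_filter(g12, k); g22 <- sep_filter(g22, k)
  hy <- sep_filter(hy, k); hx <- sep_filter(hx, k)

  reg <- 1e-4 * mean(g11 + g22) + 1e-12
  g11 <- g11 + reg; g22 <- g22 + reg
  det <- g11 * g22 - g12 * g12
  out <- array(0, c(h, w, 2L))
  out[, , 1L] <- (g22 * hy - g12 * hx) / det
  out[, , 2L] <- (g11 * hx - g12 * hy) / det
  out
}

#' Dense Farneback optical flow between two slices
#'
#' Estimates the motion field from `slice_a` to `slice_b` (see the module
#' notes above for the exact semantics): `warp(slice_b, flow)` approximates
#' `slice_a`.  Both images are linearly rescaled together to `[0, 255]`
#' before estimation.
#'
#' @param slice_a,slice_b numeric matrices of equal shape.
#' @param params a [flow_params()] object.
#' @param direction,source_index metadata stored on the returned field.
#' @return a [flow_field()].
#' @export
farneback_flow <- function(slice_a, slice_b, params = flow_params(),
                           direction = "to_next", source_index = NA_integer_) {
  if (!identical(dim(slice_a), dim(slice_b))) {
    stop("farneback_flow: shape mismatch", call. = FALSE)
  }
  lo <- min(slice_a, slice_b); hi <- max(slice_a, slice_b)
  if (hi > lo) {
    slice_a <- (slice_a - lo) / (hi - lo) * 255
    slice_b <- (slice_b - lo) / (hi - lo) * 255
  } else {
    return(flow_field(array(0, c(dim(slice_a), 2L)), direction, source_index))
  }

  # pyramid (level 1 = full resolution), capped so the coarsest level
  # still supports the expansion window
  pyr_a <- list(slice_a); pyr_b <- list(slice_b)
  min_dim <- 4L * params$poly_n
  for (l in seq_len(params$levels - 1L)) {
    prev <- pyr_a[[l]]
    nh <- max(round(nrow(prev) * params$pyr_scale), 3)
    nw <- max(round(ncol(prev) * params$pyr_scale), 3)
    if (min(nh, nw) < min_dim) break
    blur <- gaussian_kernel(1 / params$pyr_scale * 0.5)
    pyr_a[[l + 1L]] <- resize_slice(sep_filter(pyr_a[[l]], blur), nh, nw, "linear")
    pyr_b[[l + 1L]] <- resize_slice(sep_filter(pyr_b[[l]], blur), nh, nw, "linear")
  }

  d <- NULL
  for (l in rev(seq_along(pyr_a))) {
    a <- pyr_a[[l]]; b <- pyr_b[[l]]
    if (is.null(d)) {
      d <- array(0, c(dim(a), 2L))
    } else {
      ratio_h <- nrow(a) / nrow(d)
      ratio_w <- ncol(a) / ncol(d)
      up <- array(0, c(dim(a), 2L))
      up[, , 1L] <- resize_slice(d[, , 1L], nrow(a), ncol(a), "linear") * ratio_h
      up[, , 2L] <- resize_slice(d[, , 2L], nrow(a), ncol(a), "linear") * ratio_w
      d <- up
    }
    p1 <- poly_expansion(a, params$poly_n, params$poly_sigma)
    p2 <- poly_expansion(b, params$poly_n, params$poly_sigma)
    for (it in seq_len(params$iterations)) {
      d <- flow_update(p1, p2, d, params$winsize)
    }
  }
  flow_field(d, direction, source_index)
}

## ---- flow cache -----------------------------------------------------------

#' Precompute interslice flow fields for a volume
#'
#' For every slice `n`, estimates the fields `f[n, n-1]` (direction
#' `to_prev`) and `f[n, n+1]` (`to_next`) where the neighbour exists, such
#' that `warp(slice_n, f[n, k])` approximates `slice_k`.  Flows are estimated
#' on the ground-truth slices once, ahead of training.
#'
#' @param v a [normalized_volume()] or an H x W x Z array of slices.
#' @param params a [flow_params()] object.
#' @return object of class `flow_cache`: a list with one `(to_prev, to_next)`
#'   pair per slice (`NULL` where the neighbour does not exist).
#' @export
build_flow_cache <- function(v, params = flow_params()) {
  slices <- if (inherits(v, "normalized_volume")) v$slices else v
  z <- dim(slices)[3]
  if (is.na(z) || z < 2L) {
    stop("build_flow_cache: need at least 2 slices", call. = FALSE)
  }
  fields <- vector("list", z)
  for (n in seq_len(z)) {
    to_prev <- if (n > 1L) {
      farneback_flow(slices[, , n - 1L], slices[, , n], params,
                     direction = "to_prev", source_index = n)
    }
    to_next <- if (n < z) {
      farneback_flow(slices[, , n + 1L], slices[, , n], params,
                     direction = "to_next", source_index = n)
    }
    fields[[n]] <- list(to_prev = to_prev, to_next = to_next)
  }
  structure(list(fields = fields, n_slices = z), class = "flow_cache")
}

#' Count the flow fields stored in a cache
#' @param cache a [build_flow_cache()] result.
#' @return integer.
#' @export
flow_cache_size <- function(cache) {
  sum(vapply(cache$fields,
             function(f) (!is.null(f$to_prev)) + (!is.null(f$to_next)),
             numeric(1)))
}

#' Save / load a flow cache
#'
#' Caches are stored as one compressed serialized object per volume.
#'
#' @param cache a `flow_cache`.
#' @param path file path.
#' @return `save_flow_cache` returns `path` invisibly; `load_flow_cache`
#'   returns the cache.
#' @export
save_flow_cache <- function(cache, path) {
  saveRDS(cache, path, compress = "gzip")
  invisible(path)
}

#' @rdname save_flow_cache
#' @export
load_flow_cache <- function(path) readRDS(path)
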