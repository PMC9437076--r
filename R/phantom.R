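## Synthetic paired pelvis phantoms.
##
## Each phantom is a co-registered pseudo-CT / pseudo-MR pair: an elliptical
## body contour over an air background, two bone-like discs (femoral heads,
## ~800-1200 HU), a bladder-like ellipse (~0-30 HU), a rectum-like ellipse
## with an air core (~ -900 HU), and textured soft tissue (~20-80 HU).  The
## MR is a monotone but nonlinear per-tissue remapping (bone contrast
## inverted relative to CT) with its own texture, a smooth bias field,
## noise, and sparse bright outliers that give the 99th-percentile
## truncation something to remove.
##
## The body centre follows a smooth random walk across slices; textures are
## analytic band-limited fields evaluated at the drifted coordinates and
## tissue boundaries carry a partial-volume transition, so adjacent slices
## differ by small, flow-recoverable displacements.  Semi-axes follow their
## own small random walk.

#' Phantom specification
#'
#' @param n_slices number of axial slices (at least 5 so trimming leaves one).
#' @param height,width slice dimensions in pixels.
#' @param drift_step maximum per-slice drift of the body centre, in pixels.
#' @param noise_sigma_ct CT noise standard deviation (HU).
#' @param noise_sigma_mr MR noise standard deviation (raw units).
#' @param seed integer seed; generation is bit-reproducible given the spec.
#' @param patient_id,site_id provenance attached to the generated volumes.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(n_slices = 12L, height = 64L, width = 64L,
                         drift_step = 1.0, noise_sigma_ct = 10,
                         noise_sigma_mr = 8, seed = 1L,
                         patient_id = "phantom", site_id = 1L) {
  stopifnot(n_slices >= 5L, height >= 32L, width >= 32L, drift_step >= 0)
  structure(list(n_slices = as.integer(n_slices), height = as.integer(height),
                 width = as.integer(width), drift_step = drift_step,
                 noise_sigma_ct = noise_sigma_ct,
                 noise_sigma_mr = noise_sigma_mr, seed = as.integer(seed),
                 patient_id = patient_id, site_id = as.integer(site_id)),
            class = "phantom_spec")
}

smooth_z <- function(x) {
  n <- length(x)
  if (n < 3L) return(x)
  out <- x
  out[2:(n - 1)] <- 0.25 * x[1:(n - 2)] + 0.5 * x[2:(n - 1)] + 0.25 * x[3:n]
  out
}

# keep a random walk inside [-r, r] by reflecting at the boundary (clamping
# would flatten the walk and kill the interslice motion it exists to create)
reflect_walk <- function(x, r = 3) {
  abs(((x + r) %% (4 * r)) - 2 * r) - r
}

# band-limited random texture: a sum of cosines with random orientation,
# wavelength and phase.  Evaluated analytically at continuous coordinates,
# so drifting anatomy carries its texture exactly (no resampling smoothing
# enters the construction).
make_cosine_texture <- function(sd_target, n_comp = 40L, wl = c(6, 18)) {
  kmag <- 2 * pi / stats::runif(n_comp, wl[1], wl[2])
  th <- stats::runif(n_comp, 0, 2 * pi)
  amp <- stats::rnorm(n_comp)
  list(ky = kmag * sin(th), kx = kmag * cos(th),
       phase = stats::runif(n_comp, 0, 2 * pi),
       amp = amp * sd_target / sqrt(sum(amp^2) / 2))
}

# texture of slice n at pixel p is T(p - drift_n): anatomy drifting by +d
# carries its texture along
eval_texture <- function(tx, h, w, dy, dx) {
  yy <- matrix(seq_len(h), h, w) - dy
  xx <- matrix(rep(seq_len(w), each = h), h, w) - dx
  s <- matrix(0, h, w)
  for (k in seq_along(tx$amp)) {
    s <- s + tx$amp[k] * cos(tx$ky[k] * yy + tx$kx[k] * xx + tx$phase[k])
  }
  s
}

# soft (partial-volume) ellipse coverage: ~1.5 px linear transition at the
# boundary, so sub-pixel drift of a contour is representable on the grid
# and remains flow-recoverable; binary masks are the 0.5-threshold of this
ellipse_cov <- function(h, w, cy, cx, ry, rx, edge_px = 1.5) {
  rr <- (row(matrix(0, h, w)) - cy) / ry
  cc <- (col(matrix(0, h, w)) - cx) / rx
  rho <- sqrt(rr^2 + cc^2)
  # signed distance to the boundary in approximate pixels
  d <- (1 - rho) * min(ry, rx)
  pmin(pmax(d / edge_px + 0.5, 0), 1)
}

ellipse_mask <- function(h, w, cy, cx, ry, rx) {
  (ellipse_cov(h, w, cy, cx, ry, rx) > 0.5) * 1
}

#' Generate one paired CT/MR phantom volume
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `ct` and `mr` (both [raw_volume()]), `body_mask`
#'   (H x W x Z binary array) and `organs` (named list of binary organ masks:
#'   `femoral_head_l`, `femoral_head_r`, `bladder`, `rectum`).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height; w <- spec$width; z <- spec$n_slices
  with_seed(spec$seed, {
    # smooth drift of the body centre, reflected at +/-3 px so structures
    # stay in frame without the walk ever going flat
    drift_y <- reflect_walk(smooth_z(cumsum(stats::runif(z, -1, 1) * spec$drift_step)))
    drift_x <- reflect_walk(smooth_z(cumsum(stats::runif(z, -1, 1) * spec$drift_step)))

    # per-patient geometry; semi-axes follow their own small smooth random
    # walk (anatomy is not rigid) kept well below the positional drift so
    # interslice change stays flow-recoverable
    a_frac <- stats::runif(1, 0.36, 0.42) # column semi-axis / width
    b_frac <- stats::runif(1, 0.30, 0.36) # row semi-axis / height
    a_walk <- pmin(pmax(smooth_z(cumsum(stats::runif(z, -1, 1) * 0.2)), -1), 1)
    b_walk <- pmin(pmax(smooth_z(cumsum(stats::runif(z, -1, 1) * 0.2)), -1), 1)

    soft_tex <- make_cosine_texture(12)
    bone_tex <- make_cosine_texture(80)
    mr_tex <- make_cosine_texture(40, wl = c(5, 14))

    ct <- array(0, c(h, w, z)); mr <- array(0, c(h, w, z))
    body <- array(0, c(h, w, z))
    organs <- list(femoral_head_l = array(0, c(h, w, z)),
                   femoral_head_r = array(0, c(h, w, z)),
                   bladder = array(0, c(h, w, z)),
                   rectum = array(0, c(h, w, z)))

    rowg <- row(matrix(0, h, w)); colg <- col(matrix(0, h, w))
    bias <- 1 + 0.15 * sin(pi * rowg / h) * cos(pi * colg / w)

    for (n in seq_len(z)) {
      cy <- h / 2 + drift_y[n]
      cx <- w / 2 + drift_x[n]
      a <- a_frac * w + a_walk[n]
      b <- b_frac * h + b_walk[n]
      rb <- 0.16 * min(a, b)

      # partial-volume coverages (soft edges) and their binary masks
      cv_bd <- ellipse_cov(h, w, cy, cx, b, a)
      cv_bl <- ellipse_cov(h, w, cy + 0.15 * b, cx - 0.45 * a, rb, rb)
      cv_br <- ellipse_cov(h, w, cy + 0.15 * b, cx + 0.45 * a, rb, rb)
      cv_bladder <- ellipse_cov(h, w, cy - 0.30 * b, cx, 0.20 * b, 0.28 * a)
      cv_rectum <- ellipse_cov(h, w, cy + 0.45 * b, cx, 0.13 * b, 0.15 * a)
      cv_core <- ellipse_cov(h, w, cy + 0.45 * b, cx,
                             0.6 * 0.13 * b, 0.6 * 0.15 * a)
      bd <- (cv_bd > 0.5) * 1
      bl <- (cv_bl > 0.5) * 1
      br <- (cv_br > 0.5) * 1
      bladder <- (cv_bladder > 0.5) * 1
      rectum <- (cv_rectum > 0.5) * 1

      if (any((bl + br + bladder + rectum) * (1 - bd) > 0)) {
        stop("generate_phantom: organ placed outside the body contour",
             call. = FALSE)
      }
      if (max(bl + br + bladder + rectum) > 1) {
        stop("generate_phantom: organ masks overlap", call. = FALSE)
      }

      st <- eval_texture(soft_tex, h, w, drift_y[n], drift_x[n])
      bt <- eval_texture(bone_tex, h, w, drift_y[n], drift_x[n])
      mt <- eval_texture(mr_tex, h, w, drift_y[n], drift_x[n])

      # layered compositing over the coverages
      blend <- function(base, value, cov) base * (1 - cov) + value * cov
      ct_sl <- matrix(-1000, h, w)
      ct_sl <- blend(ct_sl, 50 + pmin(pmax(st, -30), 30), cv_bd)
      ct_sl <- blend(ct_sl, 15 + pmin(pmax(st / 3, -15), 15), cv_bladder)
      ct_sl <- blend(ct_sl, 1000 + pmin(pmax(bt, -200), 200), cv_bl)
      ct_sl <- blend(ct_sl, 1000 + pmin(pmax(bt, -200), 200), cv_br)
      ct_sl <- blend(ct_sl, -900, cv_core)

      mr_sl <- matrix(30, h, w)
      mr_sl <- blend(mr_sl, 500 + pmin(pmax(mt, -120), 120), cv_bd)
      mr_sl <- blend(mr_sl, 850 + mt / 4, cv_bladder)
      mr_sl <- blend(mr_sl, 120 + mt / 8, cv_bl)
      mr_sl <- blend(mr_sl, 120 + mt / 8, cv_br)
      mr_sl <- blend(mr_sl, 40, cv_core)
      mr_sl <- mr_sl * bias

      ct[, , n] <- ct_sl + stats::rnorm(h * w, 0, spec$noise_sigma_ct)
      mr[, , n] <- pmax(mr_sl + stats::rnorm(h * w, 0, spec$noise_sigma_mr), 0)
      body[, , n] <- bd
      organs$femoral_head_l[, , n] <- bl
      organs$femoral_head_r[, , n] <- br
      organs$bladder[, , n] <- bladder
      organs$rectum[, , n] <- rectum
    }

    # sparse bright MR outliers inside the body (exercise the 99th-percentile cap)
    inside <- which(body == 1)
    n_out <- max(1L, round(0.002 * length(inside)))
    spikes <- sample(inside, n_out)
    mr[spikes] <- mr[spikes] * 3

    list(ct = raw_volume(ct, "CT", body, spec$patient_id, spec$site_id),
         mr = raw_volume(mr, "MR", body, spec$patient_id, spec$site_id),
         body_mask = body, organs = organs)
  })
}

#' Generate a multi-patient, multi-site phantom cohort
#'
#' Per-patient phantom specs are derived from the cohort seed through a
#' fixed hierarchical scheme (`patient_seed = (seed * 10007 + i * 101) mod
#' (2^31 - 1)`), so the cohort is bit-reproducible while patients differ in
#' geometry and texture.
#'
#' @param n_patients number of patients.
#' @param site_assignment integer vector of site ids (1-3), recycled to
#'   `n_patients`.  Default: the 8/7/4 three-site layout when
#'   `n_patients == 19`, otherwise round-robin over sites 1..3.
#' @param seed cohort seed.
#' @param n_slices,size per-volume slice count and slice side length.
#' @param ... further arguments passed to [phantom_spec()].
#' @return list of [generate_phantom()] results, one per patient.
#' @export
generate_cohort <- function(n_patients, site_assignment = NULL, seed = 1L,
                            n_slices = 12L, size = 64L, ...) {
  stopifnot(n_patients >= 1L)
  if (is.null(site_assignment)) {
    site_assignment <- if (n_patients == 19L) {
      c(rep(1L, 8), rep(2L, 7), rep(3L, 4))
    } else {
      rep_len(1:3, n_patients)
    }
  }
  site_assignment <- rep_len(as.integer(site_assignment), n_patients)
  lapply(seq_len(n_patients), function(i) {
    ps <- (as.numeric(seed) * 10007 + i * 101) %% 2147483647
    generate_phantom(phantom_spec(
      n_slices = n_slices, height = size, width = size,
      seed = as.integer(ps),
      patient_id = sprintf("phantom_%02d", i),
      site_id = site_assignment[i], ...))
  })
}
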