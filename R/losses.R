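## Loss terms for the four adversarial objectives.
##
## All losses are pure functions of batches of real/synthesized slices (or
## of discriminator scores) and are exact, so they can be checked against
## brute-force loop oracles.  Expectations are realized as batch means.

#' Loss-weight presets for the four model variants
#'
#' The presets pin the reference weighting of the generator objective:
#' * `cyclegan`:   lambda_cycle = 10
#' * `structcgan`: lambda_cycle = 8, lambda_ssim = 2
#' * `flowcgan`:   lambda_cycle = 8, lambda_flow = 2
#' * `sfcgan`:     lambda_cycle = 6, lambda_ssim = 2, lambda_flow = 2
#'
#' Custom weights may be supplied but must be consistent with the variant:
#' a variant that does not use a term requires its weight to be zero.
#'
#' @param variant one of `"cyclegan"`, `"structcgan"`, `"flowcgan"`, `"sfcgan"`.
#' @param lambda_cycle,lambda_ssim,lambda_flow optional overrides.
#' @return list of class `loss_weights`.
#' @export
loss_weights <- function(variant = c("cyclegan", "structcgan", "flowcgan", "sfcgan"),
                         lambda_cycle = NULL, lambda_ssim = NULL,
                         lambda_flow = NULL) {
  variant <- match.arg(variant)
  preset <- switch(variant,
    cyclegan   = c(cycle = 10, ssim = 0, flow = 0),
    structcgan = c(cycle = 8,  ssim = 2, flow = 0),
    flowcgan   = c(cycle = 8,  ssim = 0, flow = 2),
    sfcgan     = c(cycle = 6,  ssim = 2, flow = 2)
  )
  w <- list(
    lambda_cycle = if (is.null(lambda_cycle)) preset[["cycle"]] else lambda_cycle,
    lambda_ssim  = if (is.null(lambda_ssim))  preset[["ssim"]]  else lambda_ssim,
    lambda_flow  = if (is.null(lambda_flow))  preset[["flow"]]  else lambda_flow,
    variant = variant
  )
  uses_ssim <- variant %in% c("structcgan", "sfcgan")
  uses_flow <- variant %in% c("flowcgan", "sfcgan")
  if (!uses_ssim && w$lambda_ssim != 0) {
    stop("variant '", variant, "' does not use an SSIM term; lambda_ssim must be 0",
         call. = FALSE)
  }
  if (!uses_flow && w$lambda_flow != 0) {
    stop("variant '", variant, "' does not use a flow term; lambda_flow must be 0",
         call. = FALSE)
  }
  structure(w, class = "loss_weights")
}

#' Least-squares adversarial generator loss
#'
#' `E[(D_MR(sMR) - 1)^2] + E[(D_CT(sCT) - 1)^2]`: the generators are rewarded
#' when the discriminators score their outputs as real (label 1).
#'
#' @param d_mr_on_smr,d_ct_on_sct numeric vectors of discriminator scores on
#'   synthesized MR and synthesized CT batches.
#' @return non-negative scalar.
#' @export
lsgan_generator_loss <- function(d_mr_on_smr, d_ct_on_sct) {
  if (length(d_mr_on_smr) == 0L || length(d_ct_on_sct) == 0L) {
    stop("lsgan_generator_loss: empty score batch", call. = FALSE)
  }
  mean((d_mr_on_smr - 1)^2) + mean((d_ct_on_sct - 1)^2)
}

#' Cycle-consistency loss
#'
#' Mean L1 between each input and its round-trip reconstruction, summed over
#' the two modalities.
#'
#' @param ct,rec_ct real CT batch and its reconstruction `G_CT(G_MR(CT))`.
#' @param mr,rec_mr real MR batch and its reconstruction `G_MR(G_CT(MR))`.
#' @return non-negative scalar.
#' @export
cycle_loss <- function(ct, rec_ct, mr, rec_mr) {
  if (!identical(dim(ct), dim(rec_ct)) || !identical(dim(mr), dim(rec_mr))) {
    stop("cycle_loss: shape mismatch", call. = FALSE)
  }
  mean(abs(rec_ct - ct)) + mean(abs(rec_mr - mr))
}

#' Least-squares discriminator loss for one modality
#'
#' `E[(D(real) - 1)^2] + E[(D(fake))^2]`: the discriminator should score real
#' images as 1 and synthesized images as 0.
#'
#' @param d_real,d_fake score vectors on real and synthesized batches.
#' @return non-negative scalar.
#' @export
discriminator_loss <- function(d_real, d_fake) {
  if (length(d_real) == 0L || length(d_fake) == 0L) {
    stop("discriminator_loss: empty score batch", call. = FALSE)
  }
  mean((d_real - 1)^2) + mean(d_fake^2)
}

#' Net discriminator loss
#'
#' Average of the CT-modality and MR-modality discriminator losses.
#'
#' @param loss_d_ct,loss_d_mr per-modality discriminator losses.
#' @return scalar.
#' @export
discriminator_net_loss <- function(loss_d_ct, loss_d_mr) {
  (loss_d_ct + loss_d_mr) / 2
}

#' Structural-similarity loss over both modalities
#'
#' `1 - (SSIM_CT + SSIM_MR) / 2`, where each SSIM index is the windowed
#' index of [ssim_index()], averaged over the batch when 3D arrays
#' (H, W, B) are supplied.  Inputs are expected on a `[0, 1]` scale.
#'
#' @param ct,sct real and synthesized CT (matrix or H x W x B array).
#' @param mr,smr real and synthesized MR.
#' @param c an [ssim_constants()] object.
#' @return scalar in `[0, 2]`.
#' @export
ssim_loss <- function(ct, sct, mr, smr, c = ssim_constants()) {
  s_ct <- ssim_index_batch(ct, sct, c)
  s_mr <- ssim_index_batch(mr, smr, c)
  1 - (s_ct + s_mr) / 2
}

ssim_index_batch <- function(x, y, c) {
  if (is.matrix(x) || is.null(dim(x)) || length(dim(x)) == 2L) {
    return(ssim_index(x, y, c))
  }
  d <- dim(x)
  if (!identical(d, dim(y))) stop("ssim: shape mismatch", call. = FALSE)
  nb <- prod(d[-(1:2)])
  xs <- array(x, c(d[1], d[2], nb))
  ys <- array(y, c(d[1], d[2], nb))
  mean(vapply(seq_len(nb),
              function(i) ssim_index(xs[, , i], ys[, , i], c), numeric(1)))
}

#' Dual-sided optical-flow consistency loss for one slice
#'
#' Warps the synthesized slice `n` towards each available ground-truth
#' neighbour using the precomputed flow fields and accumulates the mean L1
#' residual, summed over the available directions.  Boundary slices carry
#' only their one-sided term, unscaled.
#'
#' @param s_syn_n synthesized slice `n` (matrix).
#' @param gt_prev,gt_next ground-truth neighbour slices (`NULL` when the
#'   slice is the first/last of its volume).
#' @param f_to_prev,f_to_next [flow_field()] objects from the flow cache for
#'   slice `n` (`NULL` in step with the missing neighbour).
#' @return non-negative scalar.
#' @export
flow_loss <- function(s_syn_n, gt_prev = NULL, gt_next = NULL,
                      f_to_prev = NULL, f_to_next = NULL) {
  if (is.null(gt_prev) && is.null(gt_next)) {
    stop("flow_loss: both neighbours missing", call. = FALSE)
  }
  loss <- 0
  if (!is.null(gt_prev)) {
    loss <- loss + mean(abs(warp(s_syn_n, f_to_prev) - gt_prev))
  }
  if (!is.null(gt_next)) {
    loss <- loss + mean(abs(warp(s_syn_n, f_to_next) - gt_next))
  }
  loss
}

#' Net generator objective for a model variant
#'
#' Weighted sum of the adversarial, cycle, SSIM and flow terms with the
#' variant's weights: `GAN + lambda_cycle * cycle + lambda_ssim * ssim +
#' lambda_flow * flow`, terms with zero weight omitted.
#'
#' @param terms named list with elements `gan`, `cycle` and, as the variant
#'   requires, `ssim` and/or `flow`.
#' @param w a [loss_weights()] object.
#' @return scalar.
#' @export
generator_net_loss <- function(terms, w) {
  stopifnot(inherits(w, "loss_weights"))
  need <- c("gan", "cycle",
            if (w$lambda_ssim != 0) "ssim",
            if (w$lambda_flow != 0) "flow")
  missing <- setdiff(need, names(terms))
  if (length(missing)) {
    stop("generator_net_loss: variant '", w$variant, "' requires term(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  total <- terms$gan + w$lambda_cycle * terms$cycle
  if (w$lambda_ssim != 0) total <- total + w$lambda_ssim * terms$ssim
  if (w$lambda_flow != 0) total <- total + w$lambda_flow * terms$flow
  total
}
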