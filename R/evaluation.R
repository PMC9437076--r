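## Hounsfield-unit evaluation: ME, MAE and PSNR inside the body contour and
## within each organ delineation, with across-volume mean +/- SD aggregation.
##
## ME and MAE are computed after denormalizing 16-bit values back to HU;
## PSNR is computed on the 16-bit scale with MAX_I = 65535.  Two PSNR modes
## exist because the literal formula divides MAX_I by the MSE while the
## conventional definition divides by the RMSE; the conventional "standard"
## mode is the default (see the methods vignette).

#' Signed mean error over a mask
#'
#' `mean(CT - sCT)` over masked voxels; positive values mean the synthetic
#' CT underestimates.
#'
#' @param ct,sct aligned numeric volumes (HU).
#' @param mask binary array of the same shape.
#' @return scalar (HU).
#' @export
mean_error <- function(ct, sct, mask) {
  check_metric_inputs(ct, sct, mask)
  mean(ct[mask == 1] - sct[mask == 1])
}

#' Mean absolute error over a mask
#'
#' @inheritParams mean_error
#' @return scalar (HU).
#' @export
mean_absolute_error <- function(ct, sct, mask) {
  check_metric_inputs(ct, sct, mask)
  mean(abs(ct[mask == 1] - sct[mask == 1]))
}

check_metric_inputs <- function(ct, sct, mask) {
  if (!identical(dim(ct), dim(sct)) || !identical(dim(ct), dim(mask))) {
    stop("metrics: volumes and mask must share one shape", call. = FALSE)
  }
  if (!any(mask == 1)) {
    stop("metrics: empty mask", call. = FALSE)
  }
}

#' Peak signal-to-noise ratio on the 16-bit scale
#'
#' `mode = "paper"` computes `20 log10(65535 / MSE)` literally; `mode =
#' "standard"` computes the conventional `20 log10(65535 / sqrt(MSE))`.
#' Identical inputs give `Inf` as a sentinel.
#'
#' @param ct_u16,sct_u16 volumes on the `[0, 65535]` scale.
#' @param mask binary array.
#' @param mode `"standard"` (default) or `"paper"`.
#' @return scalar (dB).
#' @export
psnr <- function(ct_u16, sct_u16, mask, mode = c("standard", "paper")) {
  mode <- match.arg(mode)
  check_metric_inputs(ct_u16, sct_u16, mask)
  mse <- mean((ct_u16[mask == 1] - sct_u16[mask == 1])^2)
  if (mse == 0) return(Inf)
  denom <- if (mode == "paper") mse else sqrt(mse)
  20 * log10(65535 / denom)
}

#' Evaluate one synthesized volume against its ground truth
#'
#' Computes ME and MAE in HU (after denormalization through `rec`) and PSNR
#' on the 16-bit scale, over the body contour and within each organ
#' delineation.  Organs whose mask is empty in this volume are skipped with
#' a warning.
#'
#' @param ct_u16,sct_u16 ground-truth and synthesized volumes on the 16-bit
#'   scale, aligned.
#' @param body_mask binary body-contour array.
#' @param organs optional named list of binary organ masks.
#' @param rec the CT [normalization_record()] for HU recovery.
#' @param psnr_mode passed to [psnr()].
#' @return a `metrics_report` data frame with columns `region`, `ME_HU`,
#'   `MAE_HU`, `PSNR_dB`, `n_voxels`.
#' @export
evaluate_volume <- function(ct_u16, sct_u16, body_mask, organs = NULL,
                            rec, psnr_mode = "standard") {
  ct_hu <- denormalize_to_hu(ct_u16, rec)
  sct_hu <- denormalize_to_hu(sct_u16, rec)
  regions <- c(list(body = body_mask), organs)
  rows <- list()
  for (rn in names(regions)) {
    m <- regions[[rn]]
    if (!any(m == 1)) {
      warning("evaluate_volume: region '", rn, "' is empty; skipped",
              call. = FALSE)
      next
    }
    rows[[rn]] <- data.frame(
      region = rn,
      ME_HU = mean_error(ct_hu, sct_hu, m),
      MAE_HU = mean_absolute_error(ct_hu, sct_hu, m),
      PSNR_dB = psnr(ct_u16, sct_u16, m, psnr_mode),
      n_voxels = sum(m == 1))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("metrics_report", "data.frame")
  out
}

#' Aggregate per-volume reports into mean +/- SD per region
#'
#' Population standard deviation across volumes (divisor `n`, not `n - 1`).
#'
#' @param reports list of [evaluate_volume()] results.
#' @return data frame with columns `region`, `metric`, `mean`, `sd`,
#'   `n_volumes`.
#' @export
aggregate_reports <- function(reports) {
  stopifnot(length(reports) >= 1L)
  all_df <- do.call(rbind, reports)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  rows <- list()
  for (rn in unique(all_df$region)) {
    sub <- all_df[all_df$region == rn, ]
    for (mt in c("ME_HU", "MAE_HU", "PSNR_dB")) {
      rows[[length(rows) + 1L]] <- data.frame(
        region = rn, metric = mt, mean = mean(sub[[mt]]),
        sd = pop_sd(sub[[mt]]), n_volumes = nrow(sub))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a metrics report as CSV
#'
#' @param report a `metrics_report` or aggregated data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}

#' Mean adjacent-slice flow residual of a volume
#'
#' For every slice with a `to_next` flow field, warps the slice towards its
#' successor and takes the mean absolute residual; the mean over slice pairs
#' summarizes interframe consistency (lower = more consistent with the
#' ground-truth motion).
#'
#' @param slices H x W x Z array.
#' @param cache a [build_flow_cache()] result (typically computed on the
#'   ground-truth volume).
#' @param mask optional binary H x W x Z array restricting the residual.
#' @return scalar.
#' @export
interframe_residual <- function(slices, cache, mask = NULL) {
  z <- dim(slices)[3]
  stopifnot(z >= 2L, cache$n_slices == z)
  vals <- numeric(0)
  for (n in seq_len(z - 1L)) {
    f <- cache$fields[[n]]$to_next
    res <- abs(warp(slices[, , n], f) - slices[, , n + 1L])
    if (!is.null(mask)) {
      m <- mask[, , n + 1L] == 1
      if (!any(m)) next
      vals <- c(vals, mean(res[m]))
    } else {
      vals <- c(vals, mean(res))
    }
  }
  mean(vals)
}
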