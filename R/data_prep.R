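## Preprocessing: raw paired MR/CT volumes -> normalized 16-bit slice corpus.
##
## Steps: background masking (0 outside the body for MR, -1024 for CT),
## intensity truncation (CT capped at 1400 HU; MR at the 99th percentile of
## in-body intensities), 16-bit min-max normalization with an invertible
## record for HU recovery, removal of the first and last two axial slices,
## bicubic resizing, and the site-based train/test split.
##
## CT uses the fixed global range [-1024, 1400] HU for the 16-bit mapping so
## HU denormalization is consistent across volumes; MR uses per-volume
## min-max after percentile truncation (the normalization exists to absorb
## scanner-dependent MR intensity variation).  Quantization rounds
## half-to-even.

CT_BACKGROUND_HU <- -1024
CT_TRUNCATION_HU <- 1400
MR_PERCENTILE <- 0.99

#' Construct a raw single-modality volume
#'
#' @param voxels H x W x Z numeric array, axial slice axis last; HU for CT,
#'   scanner-arbitrary units for MR.
#' @param modality `"CT"` or `"MR"`.
#' @param body_mask binary array, same shape as `voxels`.
#' @param patient_id character identifier.
#' @param site_id acquisition site, one of 1, 2, 3.
#' @param voxel_spacing numeric length-3 vector (mm).
#' @return object of class `raw_volume`.
#' @export
raw_volume <- function(voxels, modality = c("CT", "MR"), body_mask,
                       patient_id = "p", site_id = 1L,
                       voxel_spacing = c(1, 1, 2.5)) {
  modality <- match.arg(modality)
  if (!identical(dim(voxels), dim(body_mask))) {
    stop("raw_volume: body_mask shape must equal voxels shape", call. = FALSE)
  }
  if (length(dim(voxels)) != 3L) {
    stop("raw_volume: voxels must be a 3D array", call. = FALSE)
  }
  if (dim(voxels)[3] < 5L) {
    stop("raw_volume: need at least 5 axial slices", call. = FALSE)
  }
  if (modality == "CT" && !all(is.finite(voxels))) {
    stop("raw_volume: CT intensities must be finite", call. = FALSE)
  }
  if (!all(body_mask %in% c(0, 1))) {
    stop("raw_volume: body_mask must be binary", call. = FALSE)
  }
  structure(list(voxels = voxels, modality = modality,
                 body_mask = body_mask, patient_id = patient_id,
                 site_id = as.integer(site_id),
                 voxel_spacing = voxel_spacing),
            class = "raw_volume")
}

#' Normalization record for invertible 16-bit encoding
#'
#' @param modality `"CT"` or `"MR"`.
#' @param truncation_upper upper truncation value (HU for CT, raw units for MR).
#' @param source_min,source_max bounds of the linear map onto `[0, 65535]`.
#' @return object of class `normalization_record`.
#' @export
normalization_record <- function(modality, truncation_upper,
                                 source_min, source_max) {
  if (source_max <= source_min) {
    stop("normalization_record: source_max must exceed source_min",
         call. = FALSE)
  }
  structure(list(modality = modality, truncation_upper = truncation_upper,
                 source_min = source_min, source_max = source_max,
                 target_bits = 16L),
            class = "normalization_record")
}

#' Construct a normalized 16-bit volume
#'
#' @param slices H x W x Z integer-valued array in `[0, 65535]`.
#' @param record the [normalization_record()] that produced it.
#' @param body_mask matching binary array.
#' @param patient_id,site_id provenance, as in [raw_volume()].
#' @return object of class `normalized_volume`.
#' @export
normalized_volume <- function(slices, record, body_mask,
                              patient_id = "p", site_id = 1L) {
  if (min(slices) < 0 || max(slices) > 65535) {
    stop("normalized_volume: values must lie in [0, 65535]", call. = FALSE)
  }
  structure(list(slices = slices, record = record, body_mask = body_mask,
                 patient_id = patient_id, site_id = as.integer(site_id)),
            class = "normalized_volume")
}

#' Set out-of-body voxels to the background value
#'
#' Voxels where the body mask is 0 are set to 0 (MR) or -1024 HU (CT);
#' in-body voxels are unchanged.  Idempotent.
#'
#' @param v a [raw_volume()].
#' @return the volume with background replaced.
#' @export
mask_background <- function(v) {
  stopifnot(inherits(v, "raw_volume"))
  bg <- if (v$modality == "CT") CT_BACKGROUND_HU else 0
  v$voxels[v$body_mask == 0] <- bg
  v
}

#' Truncate the upper intensity range
#'
#' CT values are clipped to at most 1400 HU (values above are rare, chiefly
#' in femoral bone, and irrelevant to dose planning).  MR values are clipped
#' to the volume's 99th percentile to exclude outliers; the percentile is
#' computed over in-body voxels only (linear interpolation between order
#' statistics), since the zero-filled background would otherwise distort it.
#'
#' @param v a [raw_volume()], background already masked.
#' @return list with elements `volume` (truncated [raw_volume()]) and
#'   `record` (a [normalization_record()]).
#' @export
truncate_intensities <- function(v) {
  stopifnot(inherits(v, "raw_volume"))
  if (v$modality == "CT") {
    upper <- CT_TRUNCATION_HU
    v$voxels <- pmin(v$voxels, upper)
    rec <- normalization_record("CT", upper, CT_BACKGROUND_HU, upper)
  } else {
    inside <- v$voxels[v$body_mask == 1]
    if (length(inside) == 0L) {
      stop("truncate_intensities: empty body mask", call. = FALSE)
    }
    upper <- as.numeric(stats::quantile(inside, MR_PERCENTILE, type = 7,
                                        names = FALSE))
    v$voxels <- pmin(v$voxels, upper)
    lo <- min(v$voxels)
    if (upper <= lo) {
      stop("truncate_intensities: degenerate MR volume (constant intensities)",
           call. = FALSE)
    }
    rec <- normalization_record("MR", upper, lo, upper)
  }
  list(volume = v, record = rec)
}

#' Map a truncated volume onto the 16-bit range
#'
#' Linear map of `[source_min, source_max]` onto `[0, 65535]`, rounded
#' half-to-even and clipped.  The record retains the source range so
#' [denormalize_to_hu()] recovers intensities to within half a quantization
#' step.
#'
#' @param v a truncated [raw_volume()].
#' @param rec the matching [normalization_record()].
#' @return a [normalized_volume()].
#' @export
normalize_to_uint16 <- function(v, rec) {
  stopifnot(inherits(v, "raw_volume"), inherits(rec, "normalization_record"))
  scl <- 65535 / (rec$source_max - rec$source_min)
  q <- round((v$voxels - rec$source_min) * scl)
  q <- pmin(pmax(q, 0), 65535)
  normalized_volume(q, rec, v$body_mask, v$patient_id, v$site_id)
}

#' Recover source-scale intensities from 16-bit values
#'
#' @param x a [normalized_volume()] or an array of 16-bit values.
#' @param rec required when `x` is a plain array.
#' @return array on the source scale (HU for CT).
#' @export
denormalize_to_hu <- function(x, rec = NULL) {
  if (inherits(x, "normalized_volume")) {
    rec <- x$record
    x <- x$slices
  }
  stopifnot(inherits(rec, "normalization_record"))
  x / 65535 * (rec$source_max - rec$source_min) + rec$source_min
}

#' Trim end slices and resize to the working resolution
#'
#' Removes the first and last two axial slices (MR aliasing guard) and
#' resamples every remaining slice to `target x target` with bicubic
#' interpolation, re-clipping to `[0, 65535]` after interpolation overshoot.
#' The body mask is resized with nearest-neighbour sampling so it stays
#' binary.
#'
#' @param v a [normalized_volume()].
#' @param target output side length (256 in the reference pipeline).
#' @return a [normalized_volume()] with `Z - 4` slices of size
#'   `target x target`.
#' @export
trim_and_resize <- function(v, target = 256L) {
  stopifnot(inherits(v, "normalized_volume"))
  z <- dim(v$slices)[3]
  if (z < 5L) {
    stop("trim_and_resize: need at least 5 slices", call. = FALSE)
  }
  keep <- seq(3L, z - 2L)
  out <- array(0, c(target, target, length(keep)))
  msk <- array(0, c(target, target, length(keep)))
  for (i in seq_along(keep)) {
    out[, , i] <- pmin(pmax(resize_slice(v$slices[, , keep[i]], target, target,
                                         "cubic"), 0), 65535)
    msk[, , i] <- resize_slice(v$body_mask[, , keep[i]], target, target,
                               "nearest")
  }
  normalized_volume(out, v$record, msk, v$patient_id, v$site_id)
}

#' Split volumes into train and test sets by acquisition site
#'
#' Sites 2 and 3 form the training set; site 1 forms the test set.
#'
#' @param volumes list of volumes carrying a `site_id`.
#' @return list with elements `train` and `test`.
#' @export
split_by_site <- function(volumes) {
  sites <- vapply(volumes, function(v) v$site_id, integer(1))
  if (length(sites) && !all(sites %in% 1:3)) {
    stop("split_by_site: unknown site_id (must be 1, 2 or 3)", call. = FALSE)
  }
  list(train = volumes[sites %in% c(2L, 3L)],
       test = volumes[sites == 1L])
}

#' Full preprocessing of one raw volume
#'
#' Mask background, truncate, normalize to 16 bits, trim end slices and
#' resize.
#'
#' @param v a [raw_volume()].
#' @param target output slice side length.
#' @return a [normalized_volume()].
#' @export
prepare_volume <- function(v, target = 256L) {
  tr <- truncate_intensities(mask_background(v))
  trim_and_resize(normalize_to_uint16(tr$volume, tr$record), target)
}

#' Estimate a body mask from intensities (convenience fallback)
#'
#' For data arriving without a body delineation: Otsu threshold per volume
#' followed by the largest connected component per slice, via EBImage.  This
#' is a convenience extension; masks supplied with the data are preferred.
#'
#' @param voxels H x W x Z intensity array.
#' @return binary array of the same shape.
#' @export
estimate_body_mask <- function(voxels) {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    stop("estimate_body_mask requires the EBImage package", call. = FALSE)
  }
  rng <- range(voxels)
  sc <- (voxels - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
  thr <- EBImage::otsu(EBImage::Image(sc), range = c(0, 1))
  mask <- array(0, dim(voxels))
  for (z in seq_len(dim(voxels)[3])) {
    bin <- sc[, , z] > thr
    if (!any(bin)) next
    lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
    tab <- tabulate(as.integer(lab[lab > 0]))
    mask[, , z] <- (lab == which.max(tab)) * 1
  }
  mask
}

## ---- NIfTI and sidecar IO --------------------------------------------------

#' Read a raw volume from NIfTI files
#'
#' The axial slice axis is assumed to be the last NIfTI dimension.
#'
#' @param path NIfTI image path (.nii or .nii.gz).
#' @param mask_path NIfTI body-mask path.
#' @param modality,patient_id,site_id volume metadata.
#' @return a [raw_volume()].
#' @export
read_raw_volume <- function(path, mask_path, modality, patient_id = "p",
                            site_id = 1L) {
  img <- RNifti::readNifti(path)
  msk <- RNifti::readNifti(mask_path)
  spacing <- tryCatch(RNifti::pixdim(img), error = function(e) c(1, 1, 1))
  if (length(spacing) < 3) spacing <- rep_len(spacing, 3)
  raw_volume(unclass(img)[, , , drop = FALSE],
             modality = modality,
             body_mask = (unclass(msk)[, , , drop = FALSE] > 0) * 1,
             patient_id = patient_id, site_id = site_id,
             voxel_spacing = spacing[seq_len(3)])
}

#' Write a normalized volume as NIfTI plus a JSON sidecar
#'
#' The slice stack and body mask are written as NIfTI; the normalization
#' record and provenance go to `<prefix>.json`.
#'
#' @param v a [normalized_volume()].
#' @param prefix output path prefix (no extension).
#' @return character vector of the files written, invisibly.
#' @export
write_normalized_volume <- function(v, prefix) {
  stopifnot(inherits(v, "normalized_volume"))
  img_path <- paste0(prefix, ".nii.gz")
  msk_path <- paste0(prefix, "_mask.nii.gz")
  json_path <- paste0(prefix, ".json")
  RNifti::writeNifti(v$slices, img_path)
  RNifti::writeNifti(v$body_mask, msk_path)
  jsonlite::write_json(
    list(record = unclass(v$record), patient_id = v$patient_id,
         site_id = v$site_id),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(img_path, msk_path, json_path))
}

#' Read a normalized volume written by [write_normalized_volume()]
#'
#' @param prefix path prefix used at write time.
#' @return a [normalized_volume()].
#' @export
read_normalized_volume <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  rec <- normalization_record(meta$record$modality,
                              meta$record$truncation_upper,
                              meta$record$source_min, meta$record$source_max)
  slices <- unclass(RNifti::readNifti(paste0(prefix, ".nii.gz")))
  msk <- unclass(RNifti::readNifti(paste0(prefix, "_mask.nii.gz")))
  normalized_volume(array(as.numeric(slices), dim(slices)), rec,
                    array(as.numeric(msk), dim(msk)),
                    meta$patient_id, meta$site_id)
}
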