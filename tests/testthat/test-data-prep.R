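# Preprocessing: masking, truncation, 16-bit normalization, trimming,
# resizing and the site split.

make_ct <- function(voxels, mask = array(1, dim(voxels))) {
  raw_volume(voxels, "CT", mask, "p1", 2L)
}

test_that("background masking sets out-of-body voxels to 0 (MR) / -1024 (CT)", {
  vox <- array(312, c(6, 6, 5))
  mask <- array(0, c(6, 6, 5))
  mask[3:4, 3:4, ] <- 1
  ct <- mask_background(raw_volume(vox, "CT", mask))
  expect_equal(unique(as.vector(ct$voxels[mask == 0])), -1024)
  expect_equal(unique(as.vector(ct$voxels[mask == 1])), 312)

  mr_vox <- array(87, c(6, 6, 5))
  mr <- mask_background(raw_volume(mr_vox, "MR", mask))
  expect_equal(unique(as.vector(mr$voxels[mask == 0])), 0)
  expect_equal(unique(as.vector(mr$voxels[mask == 1])), 87)

  # all-ones mask leaves the volume untouched
  full <- mask_background(make_ct(vox))
  expect_identical(full$voxels, vox)

  # idempotence
  twice <- mask_background(mask_background(raw_volume(vox, "CT", mask)))
  expect_identical(twice$voxels, ct$voxels)

  expect_error(raw_volume(vox, "CT", mask[, , 1:4]), "shape")
})

test_that("CT intensities are truncated at 1400 HU", {
  vox <- array(c(2100, 900, -500, 1400), c(4, 5, 5))
  tr <- truncate_intensities(make_ct(vox))
  expect_equal(max(tr$volume$voxels), 1400)
  expect_equal(tr$record$truncation_upper, 1400)
  expect_true(all(tr$volume$voxels[vox <= 1400] == vox[vox <= 1400]))
})

test_that("MR truncation caps at the in-body 99th percentile", {
  set.seed(1)
  vox <- array(sample(0:999), c(10, 10, 10))
  mask <- array(1, dim(vox))
  mask[, , 1] <- 0 # exclude one slice from the percentile
  tr <- truncate_intensities(raw_volume(vox, "MR", mask))
  expected <- oracle_percentile(vox[mask == 1], 0.99)
  expect_equal(tr$record$truncation_upper, expected, tolerance = 1e-12)
  expect_equal(max(tr$volume$voxels), expected)

  const <- raw_volume(array(5, c(6, 6, 5)), "MR", array(1, c(6, 6, 5)))
  expect_error(truncate_intensities(const), "degenerate|constant")
})

test_that("16-bit normalization maps endpoints exactly and is monotone", {
  vox <- array(c(-1024, 1400, 188, 0), c(4, 4, 5))
  rec <- normalization_record("CT", 1400, -1024, 1400)
  nv <- normalize_to_uint16(make_ct(vox), rec)
  expect_equal(nv$slices[vox == -1024][1], 0)
  expect_equal(nv$slices[vox == 1400][1], 65535)
  # midpoint of [-1024, 1400] quantizes to 65535/2 under round-half-to-even
  expect_true(nv$slices[vox == 188][1] %in% c(32767, 32768))
  expect_equal(nv$slices[vox == 188][1], round(32767.5))

  set.seed(2)
  a <- sort(runif(100, -1024, 1400))
  va <- array(rep(a, length.out = 5 * 5 * 5), c(5, 5, 5))
  na <- normalize_to_uint16(make_ct(va), rec)
  expect_true(all(diff(na$slices[order(va)]) >= 0))

  expect_error(normalization_record("CT", 1400, 10, 10), "exceed")
})

test_that("normalize -> denormalize round-trips within one quantization step", {
  set.seed(3)
  vox <- array(runif(500, -1024, 1400), c(10, 10, 5))
  rec <- normalization_record("CT", 1400, -1024, 1400)
  nv <- normalize_to_uint16(make_ct(vox), rec)
  back <- denormalize_to_hu(nv)
  step <- (1400 - (-1024)) / 65535
  # brute-force per-voxel check
  worst <- 0
  for (i in seq_along(vox)) worst <- max(worst, abs(back[i] - vox[i]))
  expect_lt(worst, step)
  expect_lte(worst, step / 2 + 1e-12)
})

test_that("trimming drops the first and last two slices; bicubic resize", {
  set.seed(4)
  rec <- normalization_record("CT", 1400, -1024, 1400)
  mk <- function(z) {
    normalized_volume(array(runif(8 * 8 * z, 0, 65535), c(8, 8, z)), rec,
                      array(1, c(8, 8, z)))
  }
  v60 <- trim_and_resize(mk(60), target = 16L)
  expect_equal(dim(v60$slices), c(16L, 16L, 56L))

  v10 <- mk(10)
  out <- trim_and_resize(v10, target = 8L)
  expect_equal(dim(out$slices)[3], 6L)
  # index bookkeeping: output slice 1 is input slice 3 (same size, so the
  # resize is the identity map)
  expect_equal(out$slices[, , 1], v10$slices[, , 3], tolerance = 1e-9)

  # constant slices stay constant under bicubic resizing
  cv <- normalized_volume(array(1234, c(8, 8, 5)), rec, array(1, c(8, 8, 5)))
  rz <- trim_and_resize(cv, target = 20L)
  expect_equal(range(rz$slices), c(1234, 1234))
  expect_true(all(rz$body_mask %in% c(0, 1)))

  short <- normalized_volume(array(0, c(8, 8, 4)), rec, array(1, c(8, 8, 4)))
  expect_error(trim_and_resize(short), "at least 5")
})

test_that("site split: sites 2+3 train, site 1 test, and it is a partition", {
  mk <- function(site) {
    rec <- normalization_record("CT", 1400, -1024, 1400)
    normalized_volume(array(0, c(4, 4, 2)), rec, array(1, c(4, 4, 2)),
                      patient_id = paste0("s", site), site_id = site)
  }
  vols <- lapply(c(1, 2, 3, 1, 2), mk)
  sp <- split_by_site(vols)
  expect_equal(length(sp$train), 3L)
  expect_equal(length(sp$test), 2L)
  expect_true(all(vapply(sp$test, function(v) v$site_id, integer(1)) == 1L))
  expect_equal(length(sp$train) + length(sp$test), length(vols))

  empty <- split_by_site(list())
  expect_equal(lengths(empty), c(train = 0L, test = 0L))

  # the 19-volume three-site layout gives 11 train / 8 test
  vols19 <- lapply(c(rep(1, 8), rep(2, 7), rep(3, 4)), mk)
  sp19 <- split_by_site(vols19)
  expect_equal(length(sp19$train), 11L)
  expect_equal(length(sp19$test), 8L)

  bad <- mk(1); bad$site_id <- 9L
  expect_error(split_by_site(list(bad)), "site")
})

test_that("normalized volumes round-trip through NIfTI + JSON sidecar", {
  prep <- small_prepared()
  tmp <- withr::local_tempdir()
  prefix <- file.path(tmp, "p1_ct")
  write_normalized_volume(prep$pair$ct, prefix)
  back <- read_normalized_volume(prefix)
  expect_equal(back$slices, prep$pair$ct$slices, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$record$source_min, prep$pair$ct$record$source_min)
  expect_equal(back$site_id, prep$pair$ct$site_id)
})
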