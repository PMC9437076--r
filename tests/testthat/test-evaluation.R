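# HU-space metrics: ME, MAE, PSNR, per-organ evaluation and aggregation.

test_that("ME and MAE match loop oracles and the Eq sign convention", {
  set.seed(60)
  ct <- array(rnorm(8 * 8 * 3, 0, 100), c(8, 8, 3))
  sct <- ct + array(rnorm(8 * 8 * 3, 5, 30), c(8, 8, 3))
  mask <- array(rbinom(8 * 8 * 3, 1, 0.7), c(8, 8, 3))
  expect_equal(mean_error(ct, sct, mask), oracle_me(ct, sct, mask),
               tolerance = 1e-9)
  expect_equal(mean_absolute_error(ct, sct, mask), oracle_mae(ct, sct, mask),
               tolerance = 1e-9)

  expect_equal(mean_error(ct, ct, mask), 0)
  # sCT overestimating by +10 HU gives ME of -10
  expect_equal(mean_error(ct, ct + 10, mask), -10, tolerance = 1e-9)
  # half +10 / half -10: MAE 10, ME 0
  dev <- array(rep(c(10, -10), length.out = length(ct)), dim(ct))
  full <- array(1, dim(ct))
  expect_equal(mean_absolute_error(ct, ct + dev, full), 10, tolerance = 1e-9)
  expect_equal(mean_error(ct, ct + dev, full), 0, tolerance = 1e-9)

  expect_error(mean_error(ct, sct, array(0, dim(ct))), "empty")
})

test_that("MAE >= |ME| always; ME antisymmetric under swapping", {
  set.seed(61)
  for (i in 1:1000) {
    n <- sample(4:32, 1)
    ct <- array(rnorm(n), c(n, 1, 1))
    sct <- array(rnorm(n), c(n, 1, 1))
    mask <- array(1, c(n, 1, 1))
    me <- mean_error(ct, sct, mask)
    mae <- mean_absolute_error(ct, sct, mask)
    expect_gte(mae + 1e-12, abs(me))
    expect_equal(mean_error(sct, ct, mask), -me, tolerance = 1e-12)
    expect_equal(mean_absolute_error(sct, ct, mask), mae, tolerance = 1e-12)
  }
  # equality iff all signed errors share one sign
  ct <- array(c(1, 2, 3), c(3, 1, 1)); m <- array(1, c(3, 1, 1))
  expect_equal(mean_absolute_error(ct, ct - 2, m),
               abs(mean_error(ct, ct - 2, m)))
})

test_that("PSNR matches closed forms and the loop oracle in both modes", {
  m <- array(1, c(4, 4, 2))
  ct <- array(0, c(4, 4, 2))
  # paper mode: MSE = 65535 gives 0 dB
  sct <- ct + sqrt(65535)
  expect_equal(psnr(ct, sct, m, "paper"), 0, tolerance = 1e-9)
  # standard mode: constant difference 655.35 gives MAX/RMSE = 100 -> 40 dB
  expect_equal(psnr(ct, ct + 655.35, m, "standard"), 40, tolerance = 1e-9)

  set.seed(62)
  a <- array(runif(64, 0, 65535), c(4, 4, 4))
  b <- array(runif(64, 0, 65535), c(4, 4, 4))
  msk <- array(rbinom(64, 1, 0.8), c(4, 4, 4))
  mse <- oracle_mse(a, b, msk)
  expect_equal(psnr(a, b, msk, "paper"), 20 * log10(65535 / mse),
               tolerance = 1e-9)
  expect_equal(psnr(a, b, msk, "standard"), 20 * log10(65535 / sqrt(mse)),
               tolerance = 1e-9)
  expect_identical(psnr(a, a, msk), Inf) # sentinel on identical inputs
})

test_that("Gaussian HU noise yields the half-normal MAE at large n", {
  set.seed(63)
  n <- c(50, 50, 50) # 125,000 voxels
  ct <- array(runif(prod(n), -500, 1000), n)
  sigma <- 50
  sct <- ct + array(rnorm(prod(n), 0, sigma), n)
  mask <- array(1, n)
  mae <- mean_absolute_error(ct, sct, mask)
  expect_lt(abs(mae - sigma * sqrt(2 / pi)) / (sigma * sqrt(2 / pi)), 0.02)
})

test_that("evaluate_volume reports body and organ regions in HU", {
  rec <- normalization_record("CT", 1400, -1024, 1400)
  prep <- small_prepared()
  ct <- prep$pair$ct$slices
  body <- prep$pair$ct$body_mask

  # identical prediction: zero errors, sentinel PSNR
  rep0 <- evaluate_volume(ct, ct, body, rec = rec)
  expect_equal(rep0$ME_HU, 0)
  expect_equal(rep0$MAE_HU, 0)
  expect_identical(rep0$PSNR_dB, Inf)

  # constant known offset on the 16-bit scale maps to HU exactly
  step <- (1400 - (-1024)) / 65535
  sct <- pmin(ct + 100, 65535)
  rep1 <- evaluate_volume(ct, sct, body, rec = rec)
  expect_equal(rep1$MAE_HU, 100 * step, tolerance = 1e-6)
  expect_equal(rep1$ME_HU, -100 * step, tolerance = 1e-6)

  # one-voxel organ with a known error
  organ <- array(0, dim(ct)); organ[24, 24, 3] <- 1
  sct2 <- ct
  sct2[24, 24, 3] <- ct[24, 24, 3] - 5 / step # 5 HU below truth
  rep2 <- evaluate_volume(ct, sct2, body, organs = list(spot = organ), rec = rec)
  spot <- rep2[rep2$region == "spot", ]
  expect_equal(spot$MAE_HU, 5, tolerance = 1e-6)
  expect_equal(spot$ME_HU, 5, tolerance = 1e-6)
  expect_equal(spot$n_voxels, 1L)

  # empty organ: skipped with a warning, not an error
  expect_warning(
    rep3 <- evaluate_volume(ct, ct, body,
                            organs = list(missing = array(0, dim(ct))),
                            rec = rec),
    "empty")
  expect_false("missing" %in% rep3$region)
})

test_that("known organ bias moves exactly that organ's ME", {
  prep <- small_prepared()
  ct <- prep$pair$ct$slices
  body <- prep$pair$ct$body_mask
  rec <- prep$pair$ct$record
  # the fixture is prepared at its native resolution, so organ masks only
  # need the end-slice trim to align with the prepared grid
  z <- dim(prep$phantom$organs$bladder)[3]
  organs <- lapply(prep$phantom$organs, function(m) m[, , 3:(z - 2)])
  stopifnot(all(vapply(organs, sum, numeric(1)) > 0))
  step <- (rec$source_max - rec$source_min) / 65535
  sct <- ct
  sct[organs$bladder == 1] <- pmin(sct[organs$bladder == 1] + 20 / step, 65535)
  rep <- evaluate_volume(ct, sct, body, organs = organs, rec = rec)
  expect_equal(rep[rep$region == "bladder", "ME_HU"], -20, tolerance = 1e-6)
  for (other in c("femoral_head_l", "femoral_head_r", "rectum")) {
    expect_equal(rep[rep$region == other, "ME_HU"], 0, tolerance = 1e-9)
  }
})

test_that("aggregation reports mean and population SD per region", {
  mk <- function(mae, me, ps) {
    structure(data.frame(region = c("body", "organ"), ME_HU = me,
                         MAE_HU = mae, PSNR_dB = ps,
                         n_voxels = c(100L, 10L)),
              class = c("metrics_report", "data.frame"))
  }
  one <- aggregate_reports(list(mk(30, 1, 50)))
  expect_true(all(one$sd == 0))
  two <- aggregate_reports(list(mk(30, 1, 50), mk(50, 3, 54)))
  body_mae <- two[two$region == "body" & two$metric == "MAE_HU", ]
  expect_equal(body_mae$mean, 40)
  expect_equal(body_mae$sd, 10) # population SD
  same <- aggregate_reports(rep(list(mk(30, 1, 50)), 4))
  expect_true(all(same$sd == 0))
  expect_true(all(same$n_volumes == 4))
})
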