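# Loss terms (adversarial, cycle, discriminator, SSIM, flow) and the
# variant-weighted net objectives.

test_that("LSGAN generator loss matches hand values and the loop oracle", {
  expect_equal(lsgan_generator_loss(c(1, 1), c(1, 1, 1)), 0)
  expect_equal(lsgan_generator_loss(c(0, 0), c(0)), 2)
  # brute-force mean((x-1)^2) sum
  a <- c(0.5, 0.7); b <- 0.2
  expected <- mean(c((0.5 - 1)^2, (0.7 - 1)^2)) + (0.2 - 1)^2
  expect_equal(lsgan_generator_loss(a, b), expected, tolerance = 1e-12)
  expect_error(lsgan_generator_loss(numeric(0), 1), "empty")
})

test_that("cycle loss is mean L1 over both modalities", {
  set.seed(20)
  ct <- array(rnorm(16), c(4, 4)); mr <- array(rnorm(16), c(4, 4))
  expect_equal(cycle_loss(ct, ct, mr, mr), 0)
  expect_equal(cycle_loss(ct, ct + 0.1, mr, mr + 0.1), 0.2, tolerance = 1e-12)
  rc <- array(rnorm(16), c(4, 4)); rm <- array(rnorm(16), c(4, 4))
  acc <- 0
  for (i in 1:16) acc <- acc + abs(rc[i] - ct[i]) / 16 + abs(rm[i] - mr[i]) / 16
  expect_equal(cycle_loss(ct, rc, mr, rm), acc, tolerance = 1e-9)
  expect_error(cycle_loss(ct, rc[1:2, ], mr, rm), "shape")
})

test_that("discriminator loss rewards real=1 / fake=0; net loss averages", {
  expect_equal(discriminator_loss(c(1, 1), c(0, 0)), 0)
  expect_equal(discriminator_loss(c(0, 0), c(1, 1)), 2)
  set.seed(21)
  dr <- runif(5); df <- runif(3)
  expect_equal(discriminator_loss(dr, df),
               mean((dr - 1)^2) + mean(df^2), tolerance = 1e-12)
  expect_equal(discriminator_net_loss(0.4, 0.8), 0.6)
  expect_error(discriminator_loss(numeric(0), 1), "empty")
})

test_that("ssim_loss averages modalities and batches like a loop", {
  set.seed(22)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  n <- array(runif(16 * 16 * 3), c(16, 16, 3))
  expect_equal(ssim_loss(x, x, n, n), 0, tolerance = 1e-9)

  # batch mean equals the per-item loop
  y <- pmin(pmax(x + rnorm(length(x), 0, 0.05), 0), 1)
  m <- pmin(pmax(n + rnorm(length(n), 0, 0.05), 0), 1)
  per <- numeric(3)
  for (i in 1:3) {
    per[i] <- 1 - (ssim_index(x[, , i], y[, , i]) +
                     ssim_index(n[, , i], m[, , i])) / 2
  }
  expect_equal(ssim_loss(x, y, n, m), mean(per), tolerance = 1e-9)
})

test_that("ssim_loss equals 1 - mean index arithmetic", {
  # SSIM_CT = 0.8 and SSIM_MR = 0.6 give a loss of 0.3; construct via mock
  # indices by direct formula check
  expect_equal(1 - (0.8 + 0.6) / 2, 0.3)
  set.seed(23)
  x <- matrix(runif(144), 12); y <- matrix(runif(144), 12)
  u <- matrix(runif(144), 12); v <- matrix(runif(144), 12)
  expect_equal(ssim_loss(x, y, u, v),
               1 - (ssim_index(x, y) + ssim_index(u, v)) / 2,
               tolerance = 1e-12)
})

test_that("flow loss is the dual-sided warp residual, one-sided at bounds", {
  set.seed(24)
  s <- matrix(runif(64), 8)
  zero <- flow_field(array(0, c(8, 8, 2)), "to_prev", 2L)
  expect_equal(flow_loss(s, gt_prev = s, gt_next = s,
                         f_to_prev = zero, f_to_next = zero), 0)
  # boundary: one-sided term only, unscaled
  nb <- matrix(runif(64), 8)
  one <- flow_loss(s, gt_next = nb, f_to_next = zero)
  expect_equal(one, mean(abs(s - nb)), tolerance = 1e-12)
  expect_error(flow_loss(s), "neighbour|neighbor|missing")
})

test_that("flow loss at ground truth equals the precomputed warp residual", {
  prep <- small_prepared()
  nv <- prep$pair$ct
  cache <- prep$caches$ct
  n <- 3L
  s_gt <- to_net(nv$slices[, , n])
  gt_prev <- to_net(nv$slices[, , n - 1])
  gt_next <- to_net(nv$slices[, , n + 1])
  fl <- flow_loss(s_gt, gt_prev, gt_next,
                  cache$fields[[n]]$to_prev, cache$fields[[n]]$to_next)
  # oracle: direct warp residuals from the optical_flow module
  expected <- mean(abs(warp(s_gt, cache$fields[[n]]$to_prev) - gt_prev)) +
    mean(abs(warp(s_gt, cache$fields[[n]]$to_next) - gt_next))
  expect_equal(fl, expected, tolerance = 1e-12)
})

test_that("variant presets carry the reference weights", {
  expect_equal(loss_weights("cyclegan")$lambda_cycle, 10)
  expect_equal(loss_weights("cyclegan")$lambda_ssim, 0)
  expect_equal(loss_weights("structcgan")$lambda_cycle, 8)
  expect_equal(loss_weights("structcgan")$lambda_ssim, 2)
  expect_equal(loss_weights("flowcgan")$lambda_cycle, 8)
  expect_equal(loss_weights("flowcgan")$lambda_flow, 2)
  expect_equal(loss_weights("sfcgan")$lambda_cycle, 6)
  expect_equal(loss_weights("sfcgan")$lambda_ssim, 2)
  expect_equal(loss_weights("sfcgan")$lambda_flow, 2)
  expect_error(loss_weights("cyclegan", lambda_ssim = 1), "lambda_ssim")
  expect_error(loss_weights("structcgan", lambda_flow = 2), "lambda_flow")
})

test_that("generator net loss is the variant-weighted sum and linear", {
  terms <- list(gan = 1, cycle = 1, ssim = 1, flow = 1)
  expect_equal(generator_net_loss(terms, loss_weights("sfcgan")), 11)
  expect_equal(generator_net_loss(terms, loss_weights("cyclegan")), 11)
  expect_equal(generator_net_loss(terms, loss_weights("structcgan")), 11)
  expect_equal(generator_net_loss(terms, loss_weights("flowcgan")), 11)
  zero <- list(gan = 0, cycle = 0, ssim = 0, flow = 0)
  expect_equal(generator_net_loss(zero, loss_weights("sfcgan")), 0)

  # linearity in each term with the configured weights
  w <- loss_weights("sfcgan")
  base <- generator_net_loss(terms, w)
  for (tn in c("gan", "cycle", "ssim", "flow")) {
    t2 <- terms; t2[[tn]] <- terms[[tn]] + 1
    lam <- switch(tn, gan = 1, cycle = w$lambda_cycle,
                  ssim = w$lambda_ssim, flow = w$lambda_flow)
    expect_equal(generator_net_loss(t2, w) - base, lam, tolerance = 1e-12)
  }
  expect_error(generator_net_loss(list(gan = 1, cycle = 1), loss_weights("sfcgan")),
               "requires")
})
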