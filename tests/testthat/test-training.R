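# Learning-rate schedule, history buffer, train_step and the training loop.

test_that("learning rate is constant for 100 epochs then decays linearly", {
  cfg <- train_config("cyclegan")
  expect_equal(lr_at_epoch(1, cfg), 2e-4)
  expect_equal(lr_at_epoch(50, cfg), 2e-4)
  expect_equal(lr_at_epoch(100, cfg), 2e-4) # last constant epoch (the knot)
  expect_equal(lr_at_epoch(150, cfg), 1e-4) # midpoint of the decay
  expect_equal(lr_at_epoch(101, cfg), 2e-4 * 0.99)
  expect_equal(lr_at_epoch(200, cfg), 0)    # linear to zero at the endpoint
  lrs <- vapply(1:200, lr_at_epoch, numeric(1), c = cfg)
  expect_true(all(diff(lrs) <= 0)) # non-increasing, one knot
  expect_error(lr_at_epoch(0, cfg), "range")
  expect_error(lr_at_epoch(201, cfg), "range")
  expect_error(train_config(epochs = 200L, lr_constant_epochs = 99L),
               "must equal")
})

test_that("history buffer warms up, caps at capacity, swaps at rate 1/2", {
  b <- image_buffer(50L)
  set.seed(50)
  first <- lapply(1:50, function(i) matrix(i, 2, 2))
  out <- buffer_query(b, first)
  expect_identical(out, first) # warm-up: returned unchanged
  expect_equal(buffer_size(b), 50L)

  # post-warm-up: returned-from-buffer fraction ~ 0.5 over 10,000 queries
  n_swapped <- 0L
  for (i in 1:10000) {
    fresh <- matrix(50 + i, 2, 2)
    got <- buffer_query(b, list(fresh))[[1]]
    if (!identical(got, fresh)) n_swapped <- n_swapped + 1L
    expect_true(buffer_size(b) <= 50L)
  }
  expect_lt(abs(n_swapped / 10000 - 0.5), 0.02)
  expect_equal(buffer_size(b), 50L)
})

make_tiny_dataset <- function() {
  prep <- small_prepared()
  make_training_set(list(prep$pair), list(prep$caches))
}

test_that("train_step is deterministic and respects the variant contract", {
  ds <- make_tiny_dataset()
  cfg <- tiny_train_config("cyclegan")
  st <- init_train_state(cfg)

  set.seed(1)
  r1 <- train_step(st, ds[1:2])
  set.seed(1)
  r2 <- train_step(st, ds[1:2])
  expect_identical(r1$record, r2$record)

  # cyclegan records no ssim/flow terms
  expect_false(any(c("ssim", "flow") %in% names(r1$record)))
  expect_true(all(c("gan", "cycle", "g_net", "d_ct", "d_mr", "d_net") %in%
                    names(r1$record)))

  sf <- init_train_state(tiny_train_config("sfcgan"))
  set.seed(1)
  rs <- train_step(sf, ds[1:2])
  expect_true(all(c("ssim", "flow") %in% names(rs$record)))
  expect_equal(rs$record$g_net,
               rs$record$gan + 6 * rs$record$cycle + 2 * rs$record$ssim +
                 2 * rs$record$flow, tolerance = 1e-12)

  # flow variants demand a cache
  no_flow <- lapply(ds, function(s) {
    s[c("f_ct_prev", "f_ct_next", "f_mr_prev", "f_mr_next")] <- NULL
    s
  })
  expect_error(train(tiny_train_config("flowcgan"), no_flow), "flow")
})

test_that("a short training run logs epochs, checkpoints and resumes exactly", {
  ds <- make_tiny_dataset()
  cfg <- tiny_train_config("structcgan")
  tmp <- withr::local_tempdir()
  res <- train(cfg, ds, out_dir = tmp)
  expect_equal(nrow(res$history), 2L)
  expect_true(all(c("epoch", "lr", "gan", "cycle", "ssim", "g_net", "d_net")
                  %in% names(res$history)))
  expect_true(length(res$checkpoints) >= 1L)
  expect_true(all(file.exists(res$checkpoints)))

  # resuming from the epoch-1 checkpoint reproduces epoch 2 bit-identically
  ck1 <- res$checkpoints[grepl("epoch001", res$checkpoints)]
  res2 <- train(cfg, ds, resume_from = ck1)
  expect_identical(res2$history$g_net[2], res$history$g_net[2])
  expect_identical(res2$state$g_ct$layers[[1]]$params$w,
                   res$state$g_ct$layers[[1]]$params$w)

  expect_error(train(cfg, list()), "empty")
})

test_that("generator updates descend on a toy problem", {
  ds <- make_tiny_dataset()
  cfg <- tiny_train_config("cyclegan")
  st <- init_train_state(cfg)
  set.seed(2)
  g_first <- NA; g_last <- NA
  for (k in 1:30) {
    r <- train_step(st, ds[sample.int(length(ds), 2)], lr = cfg$lr)
    st <- r$state
    if (k == 1) g_first <- r$record$g_net
    g_last <- r$record$g_net
  }
  expect_lt(g_last, g_first)
})

test_that("training configs load from YAML with variant presets", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("variant: sfcgan", "epochs: 10", "batch_size: 2", "seed: 3",
               "lr_constant_epochs: 5", "lr_decay_epochs: 5",
               "ssim:", "  c2: 0.0009"), tmp)
  cfg <- load_train_config(tmp)
  expect_equal(cfg$variant, "sfcgan")
  expect_equal(cfg$weights$lambda_cycle, 6)
  expect_equal(cfg$epochs, 10L)
  expect_equal(cfg$ssim_c$c2, 0.0009)
  expect_equal(cfg$lr, 2e-4) # default preserved
})
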