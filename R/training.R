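## Alternating generator/discriminator optimization.
##
## Each step backpropagates the variant's net generator objective through
## both generators (the cycle paths chain through the opposite generator),
## applies Adam, then updates both discriminators on the averaged
## least-squares loss using history-buffer-mediated fakes.  Everything is
## driven by a single config seed, so runs are reproducible on CPU.

#' Training configuration
#'
#' Reference settings: 200 epochs, batch size 4, Adam at learning rate
#' 0.0002 held constant for 100 epochs then decayed linearly to zero over
#' the next 100, history buffers of 50 images.  Network width (`ngf`,
#' `ndf`) and residual depth (`n_res`) are exposed so desk-scale runs can
#' use narrow nets; the reference architecture is `ngf = ndf = 64`,
#' `n_res = 9`.
#'
#' @param variant model variant (see [loss_weights()]).
#' @param epochs,batch_size,lr,lr_constant_epochs,lr_decay_epochs optimizer
#'   schedule; `lr_constant_epochs + lr_decay_epochs` must equal `epochs`.
#' @param buffer_capacity history buffer size per discriminator.
#' @param seed master seed for initialization, shuffling and buffers.
#' @param ngf,ndf,n_res network size.
#' @param checkpoint_every epoch interval between checkpoints.
#' @param ssim_c [ssim_constants()] used by SSIM variants.
#' @return list of class `train_config`.
#' @export
train_config <- function(variant = "cyclegan", epochs = 200L, batch_size = 4L,
                         lr = 2e-4, lr_constant_epochs = 100L,
                         lr_decay_epochs = 100L, buffer_capacity = 50L,
                         seed = 1L, ngf = 64L, ndf = 64L, n_res = 9L,
                         checkpoint_every = 50L, ssim_c = ssim_constants()) {
  stopifnot(epochs >= 1L, batch_size >= 1L, lr > 0, buffer_capacity >= 1L)
  if (lr_constant_epochs + lr_decay_epochs != epochs) {
    stop("train_config: lr_constant_epochs + lr_decay_epochs must equal epochs",
         call. = FALSE)
  }
  w <- loss_weights(variant)
  structure(list(variant = w$variant, weights = w, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 lr_constant_epochs = as.integer(lr_constant_epochs),
                 lr_decay_epochs = as.integer(lr_decay_epochs),
                 buffer_capacity = as.integer(buffer_capacity),
                 seed = as.integer(seed), ngf = as.integer(ngf),
                 ndf = as.integer(ndf), n_res = as.integer(n_res),
                 checkpoint_every = as.integer(checkpoint_every),
                 ssim_c = ssim_c),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Constant at `lr` through `lr_constant_epochs`, then decayed linearly:
#' `lr * (1 - (e - 100) / 100)` for epochs 101..200 under the defaults, so
#' the final epoch runs at rate 0.
#'
#' @param e epoch index in `1..epochs`.
#' @param c a [train_config()].
#' @return learning rate.
#' @export
lr_at_epoch <- function(e, c) {
  if (e < 1L || e > c$epochs) {
    stop("lr_at_epoch: epoch out of range", call. = FALSE)
  }
  if (e <= c$lr_constant_epochs) return(c$lr)
  c$lr * (1 - (e - c$lr_constant_epochs) / c$lr_decay_epochs)
}

## ---- history buffer -------------------------------------------------------

#' Create a synthesized-image history buffer
#'
#' While below capacity, incoming images are stored and returned unchanged.
#' Once full, each incoming image is, with probability 1/2, swapped against
#' a uniformly drawn stored image (the stored one is returned) or returned
#' directly.  One buffer is kept per discriminator.
#'
#' @param capacity maximum number of stored images (50 by default).
#' @return an environment of class `image_buffer`.
#' @export
image_buffer <- function(capacity = 50L) {
  b <- new.env(parent = emptyenv())
  b$capacity <- as.integer(capacity)
  b$images <- list()
  class(b) <- "image_buffer"
  b
}

#' Query the history buffer with freshly synthesized images
#'
#' @param b an [image_buffer()].
#' @param fresh list of images (arrays/matrices).
#' @return list of images of the same length, to feed the discriminator.
#' @export
buffer_query <- function(b, fresh) {
  stopifnot(inherits(b, "image_buffer"), length(fresh) > 0L)
  out <- vector("list", length(fresh))
  for (i in seq_along(fresh)) {
    if (length(b$images) < b$capacity) {
      b$images[[length(b$images) + 1L]] <- fresh[[i]]
      out[[i]] <- fresh[[i]]
    } else if (stats::runif(1) < 0.5) {
      j <- sample.int(b$capacity, 1L)
      out[[i]] <- b$images[[j]]
      b$images[[j]] <- fresh[[i]]
    } else {
      out[[i]] <- fresh[[i]]
    }
  }
  out
}

#' @export
#' @rdname image_buffer
#' @param b an [image_buffer()].
buffer_size <- function(b) length(b$images)

## ---- dataset assembly -----------------------------------------------------

#' Build paired training samples from prepared volumes and flow caches
#'
#' Each sample pairs MR slice `n` with CT slice `n` of the same patient and
#' carries its ground-truth neighbours and cached flow fields, so the flow
#' loss needs no cross-batch lookup.  Intensities are converted to the
#' network scale `[-1, 1]`.
#'
#' @param pairs list, one per patient, of `list(mr = , ct = )`
#'   [normalized_volume()] objects on a common grid.
#' @param caches optional list, one per patient, of `list(mr = , ct = )`
#'   [build_flow_cache()] results (required by flow variants).
#' @return list of training samples.
#' @export
make_training_set <- function(pairs, caches = NULL) {
  samples <- list()
  for (p in seq_along(pairs)) {
    mr <- to_net(pairs[[p]]$mr$slices)
    ct <- to_net(pairs[[p]]$ct$slices)
    z <- dim(ct)[3]
    fc <- if (!is.null(caches)) caches[[p]]
    for (n in seq_len(z)) {
      samples[[length(samples) + 1L]] <- list(
        patient = pairs[[p]]$ct$patient_id, slice = n,
        mr = mr[, , n], ct = ct[, , n],
        ct_prev = if (n > 1L) ct[, , n - 1L],
        ct_next = if (n < z) ct[, , n + 1L],
        mr_prev = if (n > 1L) mr[, , n - 1L],
        mr_next = if (n < z) mr[, , n + 1L],
        f_ct_prev = if (!is.null(fc) && n > 1L) fc$ct$fields[[n]]$to_prev,
        f_ct_next = if (!is.null(fc) && n < z) fc$ct$fields[[n]]$to_next,
        f_mr_prev = if (!is.null(fc) && n > 1L) fc$mr$fields[[n]]$to_prev,
        f_mr_next = if (!is.null(fc) && n < z) fc$mr$fields[[n]]$to_next)
    }
  }
  samples
}

## ---- train state ----------------------------------------------------------

#' Initialize networks, optimizers and buffers for training
#'
#' @param config a [train_config()].
#' @return training state (list of networks, Adam states, buffers).
#' @export
init_train_state <- function(config) {
  g_ct <- build_generator(generator_spec("G_CT", config$ngf, config$n_res),
                          seed = config$seed + 1L)
  g_mr <- build_generator(generator_spec("G_MR", config$ngf, config$n_res),
                          seed = config$seed + 2L)
  d_ct <- build_discriminator(discriminator_spec(config$ndf),
                              seed = config$seed + 3L)
  d_mr <- build_discriminator(discriminator_spec(config$ndf),
                              seed = config$seed + 4L)
  list(g_ct = g_ct, g_mr = g_mr, d_ct = d_ct, d_mr = d_mr,
       opt_g_ct = adam_new(g_ct), opt_g_mr = adam_new(g_mr),
       opt_d_ct = adam_new(d_ct), opt_d_mr = adam_new(d_mr),
       buf_ct = image_buffer(config$buffer_capacity),
       buf_mr = image_buffer(config$buffer_capacity),
       config = config, step = 0L)
}

stack_batch <- function(mats) {
  h <- nrow(mats[[1]]); w <- ncol(mats[[1]])
  array(unlist(mats, use.names = FALSE), c(h, w, 1L, length(mats)))
}

# flow-loss value and gradient for one modality over the batch; terms and
# gradient follow the dual-sided warp residual, one-sided at boundaries
flow_terms_batch <- function(syn, samples, prev_key, next_key,
                             fprev_key, fnext_key) {
  b <- length(samples)
  hw <- dim(syn)[1:2]
  npix <- prod(hw)
  total <- 0
  grad <- array(0, dim(syn))
  for (i in seq_len(b)) {
    s <- samples[[i]]
    sl <- syn[, , 1L, i]
    if (is.null(s[[prev_key]]) && is.null(s[[next_key]])) {
      stop("flow variant sample is missing its flow cache", call. = FALSE)
    }
    if (!is.null(s[[prev_key]])) {
      if (is.null(s[[fprev_key]])) {
        stop("flow variant sample is missing its flow cache", call. = FALSE)
      }
      res <- warp(sl, s[[fprev_key]]) - s[[prev_key]]
      total <- total + mean(abs(res))
      grad[, , 1L, i] <- grad[, , 1L, i] +
        warp_input_grad(sign(res) / npix, s[[fprev_key]], hw)
    }
    if (!is.null(s[[next_key]])) {
      if (is.null(s[[fnext_key]])) {
        stop("flow variant sample is missing its flow cache", call. = FALSE)
      }
      res <- warp(sl, s[[fnext_key]]) - s[[next_key]]
      total <- total + mean(abs(res))
      grad[, , 1L, i] <- grad[, , 1L, i] +
        warp_input_grad(sign(res) / npix, s[[fnext_key]], hw)
    }
  }
  list(value = total / b, grad = grad / b)
}

ssim_terms_batch <- function(real, syn, c) {
  b <- dim(real)[4]
  vals <- numeric(b)
  grad <- array(0, dim(syn))
  for (i in seq_len(b)) {
    r01 <- (real[, , 1L, i] + 1) / 2
    s01 <- (syn[, , 1L, i] + 1) / 2
    vals[i] <- ssim_index(r01, s01, c)
    # d ssim / d syn, chained through the [0,1] rescale (factor 1/2)
    grad[, , 1L, i] <- ssim_index_grad(s01, r01, c) / 2
  }
  list(value = mean(vals), grad = grad / b)
}

#' One alternating optimization step
#'
#' Runs the generator pass (synthesis, cycle reconstruction, variant loss
#' terms), backpropagates the net generator objective through both
#' generators and updates them with Adam; then updates both discriminators
#' on the averaged least-squares loss, feeding them buffer-mediated fakes.
#'
#' @param state training state from [init_train_state()].
#' @param batch list of samples from [make_training_set()].
#' @param lr learning rate for this step.
#' @return list with `state` and `record` (every component loss term).
#' @export
train_step <- function(state, batch, lr = state$config$lr) {
  cfg <- state$config
  w <- cfg$weights
  uses_ssim <- w$lambda_ssim != 0
  uses_flow <- w$lambda_flow != 0
  b <- length(batch)

  mr_x <- stack_batch(lapply(batch, `[[`, "mr"))
  ct_x <- stack_batch(lapply(batch, `[[`, "ct"))
  nel <- length(ct_x)

  f_sct <- nn_forward(state$g_ct, mr_x); sct <- f_sct$y
  f_smr <- nn_forward(state$g_mr, ct_x); smr <- f_smr$y
  f_recct <- nn_forward(state$g_ct, smr); recct <- f_recct$y
  f_recmr <- nn_forward(state$g_mr, sct); recmr <- f_recmr$y
  f_dct <- nn_forward(state$d_ct, sct)
  f_dmr <- nn_forward(state$d_mr, smr)

  gan <- lsgan_generator_loss(f_dmr$y, f_dct$y)
  cyc <- cycle_loss(ct_x, recct, mr_x, recmr)
  terms <- list(gan = gan, cycle = cyc)

  dsct <- array(0, dim(sct))
  dsmr <- array(0, dim(smr))

  # adversarial term: back through frozen discriminators (input grad only)
  bw <- nn_backward(state$d_ct, f_dct$caches, 2 * (f_dct$y - 1) / b,
                    need_grads = FALSE)
  dsct <- dsct + bw$dx
  bw <- nn_backward(state$d_mr, f_dmr$caches, 2 * (f_dmr$y - 1) / b,
                    need_grads = FALSE)
  dsmr <- dsmr + bw$dx

  # cycle term: back through the reconstruction passes
  bw_g_ct2 <- nn_backward(state$g_ct, f_recct$caches,
                          w$lambda_cycle * sign(recct - ct_x) / nel)
  dsmr <- dsmr + bw_g_ct2$dx
  bw_g_mr2 <- nn_backward(state$g_mr, f_recmr$caches,
                          w$lambda_cycle * sign(recmr - mr_x) / nel)
  dsct <- dsct + bw_g_mr2$dx

  if (uses_ssim) {
    s_ct <- ssim_terms_batch(ct_x, sct, cfg$ssim_c)
    s_mr <- ssim_terms_batch(mr_x, smr, cfg$ssim_c)
    terms$ssim <- 1 - (s_ct$value + s_mr$value) / 2
    # d(1 - (S_ct + S_mr)/2) = -grad/2 per modality
    dsct <- dsct - w$lambda_ssim * s_ct$grad / 2
    dsmr <- dsmr - w$lambda_ssim * s_mr$grad / 2
  }
  if (uses_flow) {
    fl_ct <- flow_terms_batch(sct, batch, "ct_prev", "ct_next",
                              "f_ct_prev", "f_ct_next")
    fl_mr <- flow_terms_batch(smr, batch, "mr_prev", "mr_next",
                              "f_mr_prev", "f_mr_next")
    terms$flow <- (fl_ct$value + fl_mr$value) / 2
    dsct <- dsct + w$lambda_flow * fl_ct$grad / 2
    dsmr <- dsmr + w$lambda_flow * fl_mr$grad / 2
  }

  g_net <- generator_net_loss(terms, w)

  grads_g_ct <- grads_add(bw_g_ct2$grads,
                          nn_backward(state$g_ct, f_sct$caches, dsct,
                                      need_dx = FALSE)$grads)
  grads_g_mr <- grads_add(bw_g_mr2$grads,
                          nn_backward(state$g_mr, f_smr$caches, dsmr,
                                      need_dx = FALSE)$grads)

  up <- adam_step(state$g_ct, grads_g_ct, state$opt_g_ct, lr)
  state$g_ct <- up$net; state$opt_g_ct <- up$opt
  up <- adam_step(state$g_mr, grads_g_mr, state$opt_g_mr, lr)
  state$g_mr <- up$net; state$opt_g_mr <- up$opt

  # discriminators: buffer-mediated fakes, averaged net loss
  fake_ct <- stack_batch(buffer_query(state$buf_ct,
                                      lapply(seq_len(b), function(i) sct[, , 1L, i])))
  fake_mr <- stack_batch(buffer_query(state$buf_mr,
                                      lapply(seq_len(b), function(i) smr[, , 1L, i])))

  upd_d <- function(dnet, opt, real, fake) {
    f_real <- nn_forward(dnet, real)
    f_fake <- nn_forward(dnet, fake)
    l <- discriminator_loss(f_real$y, f_fake$y)
    # net loss averages the two modalities: factor 1/2 on each gradient
    g_real <- nn_backward(dnet, f_real$caches, (f_real$y - 1) / b,
                          need_dx = FALSE)$grads
    g_fake <- nn_backward(dnet, f_fake$caches, f_fake$y / b,
                          need_dx = FALSE)$grads
    up <- adam_step(dnet, grads_add(g_real, g_fake), opt, lr)
    list(net = up$net, opt = up$opt, loss = l)
  }
  ud_ct <- upd_d(state$d_ct, state$opt_d_ct, ct_x, fake_ct)
  ud_mr <- upd_d(state$d_mr, state$opt_d_mr, mr_x, fake_mr)
  state$d_ct <- ud_ct$net; state$opt_d_ct <- ud_ct$opt
  state$d_mr <- ud_mr$net; state$opt_d_mr <- ud_mr$opt
  state$step <- state$step + 1L

  record <- c(terms, list(g_net = g_net, d_ct = ud_ct$loss, d_mr = ud_mr$loss,
                          d_net = discriminator_net_loss(ud_ct$loss, ud_mr$loss)))
  list(state = state, record = record)
}

## ---- training loop --------------------------------------------------------

#' Train a model variant
#'
#' Epoch-level shuffling, the learning-rate schedule of [lr_at_epoch()],
#' per-epoch mean loss logging and periodic checkpoints.  Fully reproducible
#' given `config$seed`; a checkpoint stores the RNG state so resuming
#' reproduces the original run bit-identically.
#'
#' @param config a [train_config()].
#' @param dataset samples from [make_training_set()].
#' @param out_dir directory for checkpoints (none written when `NULL`).
#' @param resume_from optional checkpoint path to continue from.
#' @return list with `state`, `history` (per-epoch mean of every loss term)
#'   and `checkpoints` (paths written).
#' @export
train <- function(config, dataset, out_dir = NULL, resume_from = NULL) {
  if (length(dataset) == 0L) {
    stop("train: empty dataset", call. = FALSE)
  }
  if (config$weights$lambda_flow != 0) {
    has_flow <- vapply(dataset, function(s) {
      !is.null(s$f_ct_prev) || !is.null(s$f_ct_next)
    }, logical(1))
    if (!all(has_flow)) {
      stop("train: flow variant requires flow caches for every sample",
           call. = FALSE)
    }
  }
  history <- list()
  checkpoints <- character()
  if (is.null(resume_from)) {
    state <- init_train_state(config)
    set.seed(config$seed)
    start_epoch <- 1L
  } else {
    ck <- readRDS(resume_from)
    if (!identical(ck$config, config)) {
      stop("train: checkpoint config does not match", call. = FALSE)
    }
    state <- ck$state
    assign(".Random.seed", ck$rng, envir = globalenv())
    start_epoch <- ck$epoch + 1L
    history <- ck$history
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  for (e in seq(start_epoch, config$epochs)) {
    lr <- lr_at_epoch(e, config)
    ord <- sample.int(length(dataset))
    recs <- list()
    i <- 1L
    while (i <= length(ord)) {
      idx <- ord[seq(i, min(i + config$batch_size - 1L, length(ord)))]
      st <- train_step(state, dataset[idx], lr)
      state <- st$state
      recs[[length(recs) + 1L]] <- st$record
      i <- i + config$batch_size
    }
    keys <- names(recs[[1]])
    epoch_means <- vapply(keys, function(k) {
      mean(vapply(recs, function(r) r[[k]], numeric(1)))
    }, numeric(1))
    history[[length(history) + 1L]] <-
      c(list(epoch = e, lr = lr), as.list(epoch_means))

    if (!is.null(out_dir) &&
        (e %% config$checkpoint_every == 0L || e == config$epochs)) {
      path <- file.path(out_dir, sprintf("checkpoint_epoch%03d.rds", e))
      saveRDS(list(state = state, config = config, epoch = e,
                   rng = get(".Random.seed", envir = globalenv()),
                   history = history),
              path)
      checkpoints <- c(checkpoints, path)
    }
  }
  hist_df <- do.call(rbind, lapply(history, function(h) as.data.frame(h)))
  list(state = state, history = hist_df, checkpoints = checkpoints)
}
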