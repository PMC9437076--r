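# Shared small fixtures, built once per test run.

local_cache <- new.env(parent = emptyenv())

# one small prepared phantom pair + flow caches (memoised)
small_prepared <- function() {
  if (is.null(local_cache$prep)) {
    ph <- generate_phantom(phantom_spec(n_slices = 9L, height = 48L,
                                        width = 48L, seed = 11L))
    pair <- list(ct = prepare_volume(ph$ct, target = 48L),
                 mr = prepare_volume(ph$mr, target = 48L))
    caches <- list(ct = build_flow_cache(pair$ct),
                   mr = build_flow_cache(pair$mr))
    local_cache$prep <- list(phantom = ph, pair = pair, caches = caches)
  }
  local_cache$prep
}

tiny_train_config <- function(variant, ...) {
  train_config(variant, epochs = 2L, batch_size = 2L,
               lr_constant_epochs = 1L, lr_decay_epochs = 1L,
               ngf = 2L, ndf = 2L, n_res = 1L, seed = 5L,
               checkpoint_every = 1L, ...)
}
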