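## Experiment configuration files (YAML or JSON).
##
## Config keys mirror train_config() / loss_weights() / ssim_constants();
## the variant presets are named cyclegan | structcgan | flowcgan | sfcgan.

#' Load a training configuration from YAML or JSON
#'
#' Recognized keys: `variant`, `epochs`, `batch_size`, `lr`,
#' `lr_constant_epochs`, `lr_decay_epochs`, `buffer_capacity`, `seed`,
#' `ngf`, `ndf`, `n_res`, `checkpoint_every`, and an optional `ssim` block
#' with `c1`, `c2`, `window`.  Missing keys take the [train_config()]
#' defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a [train_config()].
#' @export
load_train_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  ssim_c <- if (!is.null(raw$ssim)) {
    ssim_constants(
      c1 = raw$ssim$c1 %||% 0.0001,
      c2 = raw$ssim$c2 %||% 0.009,
      window = raw$ssim$window %||% 11L)
  } else {
    ssim_constants()
  }
  args <- raw[intersect(names(raw),
                        c("variant", "epochs", "batch_size", "lr",
                          "lr_constant_epochs", "lr_decay_epochs",
                          "buffer_capacity", "seed", "ngf", "ndf", "n_res",
                          "checkpoint_every"))]
  do.call(train_config, c(args, list(ssim_c = ssim_c)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
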