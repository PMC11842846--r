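# shared fixtures, built once per test run
.fixture_env <- new.env(parent = emptyenv())

fixture_monolayer <- function(key = "default", ...) {
  if (!exists(key, envir = .fixture_env)) {
    args <- switch(
      key,
      default = list(n_cells = 225, field_size = 360, seed = 11),
      noiseless = list(n_cells = 225, field_size = 360, seed = 11,
                       nc_noise_sd = 0, mark_noise_sd = 0,
                       pixel_noise_sd = 0),
      abort("unknown fixture key")
    )
    par <- do.call(monolayer_params, utils::modifyList(args, list(...)))
    assign(key, suppressWarnings(generate_monolayer(par)),
           envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

fixture_features <- function(key = "default") {
  fkey <- paste0(key, "_features")
  if (!exists(fkey, envir = .fixture_env)) {
    feats <- match_and_filter(extract_features(fixture_monolayer(key)))
    assign(fkey, feats, envir = .fixture_env)
  }
  get(fkey, envir = .fixture_env)
}

# assemble a labeled_monolayer from raw matrices (for hand-built cases)
make_monolayer <- function(cell_labels, nucleus_labels, channels = list(),
                           pixel_size = 1) {
  structure(
    list(cell_labels = cell_labels, nucleus_labels = nucleus_labels,
         channels = channels, pixel_size = pixel_size,
         params = NULL, n_clipped = 0L, ground_truth = NULL),
    class = "labeled_monolayer"
  )
}
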