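# Shared expensive fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

trained_unet <- function() {
  if (is.null(.fixture_env$unet)) {
    .fixture_env$unet <- toy_model_fixture("small_unet", seed = 0L)
  }
  .fixture_env$unet
}

holdout_phantoms <- function(n = 8L, shape = c(64L, 64L)) {
  lapply(seq_len(n), function(i) {
    generate_phantom(phantom_spec(shape = shape, seed = 900000L + i))
  })
}
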