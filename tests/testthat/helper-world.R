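# Shared fixtures built in code. Worlds are cached per configuration so
# the suite pays for generation once.

.world_cache <- new.env(parent = emptyenv())

cached_world <- function(..., key = NULL) {
  cfg <- world_config(...)
  key <- key %||% paste(deparse(list(...)), collapse = "")
  if (is.null(.world_cache[[key]])) {
    .world_cache[[key]] <- generate_world(cfg)
  }
  .world_cache[[key]]
}

default_world <- function() cached_world(seed = 11, key = "default")

zero_noise_world <- function() {
  cached_world(seed = 11, replicate_cv = 0, qpcr_noise_sd = 0,
               key = "zero_noise")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
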