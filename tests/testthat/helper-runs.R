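# Shared scenario runs for the acceptance suite: the full-scale presets are
# expensive, so each is computed once per test session and reused across
# test blocks.

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(preset, horizon = NULL, seed = 1) {
  key <- paste(preset, horizon %||% "default", seed, sep = "/")
  if (!exists(key, envir = .run_cache, inherits = FALSE)) {
    sc <- scenario_preset(preset, seed = seed)
    assign(key, sim_run(sc, horizon = horizon), envir = .run_cache)
  }
  get(key, envir = .run_cache, inherits = FALSE)
}

# a run of the baseline geometry with one parameter override, seed 1
cached_override_run <- function(name, overrides, horizon = NULL, seed = 1) {
  key <- paste("ov", name, horizon %||% "default", seed, sep = "/")
  if (!exists(key, envir = .run_cache, inherits = FALSE)) {
    params <- do.call(sim_params, overrides)
    sc <- scenario(name = name, params = params, seed = seed)
    assign(key, sim_run(sc, horizon = horizon), envir = .run_cache)
  }
  get(key, envir = .run_cache, inherits = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
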