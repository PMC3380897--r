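# Shared fixtures: one short nested-regime simulation reused across test
# files (built lazily, cached for the session).
.tg_cache <- new.env(parent = emptyenv())

tg_test_sim <- function(seed = 1L, duration = 2000) {
  key <- paste0("sim_", seed, "_", duration)
  if (is.null(.tg_cache[[key]])) {
    cfg <- network_config(duration = duration, seed = seed)
    .tg_cache[[key]] <- run_simulation(
      build_network(cfg),
      stimulus_protocol(onset = 1000, duration = duration - 1000))
  }
  .tg_cache[[key]]
}

# tiny network for I/O and plumbing tests (fast, still all dynamics)
tg_tiny_config <- function(seed = 1L, ...) {
  network_config(n_ex = 10, n_inf = 5, n_ins = 5, duration = 400,
                 warmup = 100, seed = seed, ...)
}

tg_tiny_sim <- function(seed = 1L, ...) {
  run_simulation(build_network(tg_tiny_config(seed, ...)),
                 stimulus_protocol(onset = 200, duration = 200))
}
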