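# Shared helpers for building small deterministic fixtures.

# Near-deterministic electric fiber: vanishing membrane noise, no latency
# spread, no jitter.
det_fiber_params <- function(...) {
  electric_fiber_params(
    relative_spread = 1e-9, latency_sd = 0,
    jitter_sd_min = 0, jitter_sd_max = 0, ...
  )
}

# Random spike ensembles on a 10-us lattice (so fast path and oracle face
# identical tie-breaking), at most `n_max` spikes per side.
random_small_ensembles <- function(seed, duration = 8e-3, n_max = 15) {
  with_seed(seed, {
    n_e <- sample(0:n_max, 1)
    n_i <- sample(0:n_max, 1)
    lat <- function(n) sort(sample.int(round(duration / 1e-5), n, replace = TRUE)) * 1e-5
    list(
      exc = spike_train(lat(n_e), duration),
      inh = spike_train(lat(n_i), duration, fiber_id = 2L)
    )
  })
}

# with_seed is internal; reuse through the namespace for test fixtures.
with_seed <- itdsim:::with_seed
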