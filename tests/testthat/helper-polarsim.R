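# Shared fixtures. The baseline run is computed once and reused; it is the
# reference state for every delta-P computation in the tests.
default_params <- polar_params()
default_grid <- polar_grid()

baseline_cache <- new.env(parent = emptyenv())

baseline_run <- function() {
  if (is.null(baseline_cache$traj)) {
    baseline_cache$traj <- simulate_polarity(default_params, default_grid,
                                             t_end = 100)
  }
  baseline_cache$traj
}

# Brute-force two-sample ECDF distance: evaluates both step functions on the
# pooled values directly from their definitions. Oracle for ks_distance().
ks_bruteforce <- function(a, u) {
  xs <- sort(c(a, u))
  max(vapply(xs, function(x) {
    abs(mean(a <= x) - mean(u <= x))
  }, numeric(1)))
}
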