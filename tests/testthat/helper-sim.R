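# Shared simulation fixtures, built once per test run and reused across
# files.  Sizes are desk-scale: large enough for stable exponent estimates,
# small enough to keep the default test run quick.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# Critical network with coupled subsampled observers; serves the scaling,
# collapse and rescue analyses.
crit_frac_sim <- function() {
  fixture("crit_frac", function() {
    simulate_network(make_params(g = 3.5), steps = 1e6, n_runs = 30,
                     sample_fractions = c(1e-4, 1e-3, 0.01, 0.1, 1),
                     seed = 20260101)
  })
}

# Strongly subcritical network (g = 3.75) with a coupled 0.1% observer.
subcrit_sim <- function() {
  fixture("subcrit", function() {
    simulate_network(make_params(g = 3.75), steps = 1e6, n_runs = 10,
                     sample_fractions = 1e-3, seed = 20260102)
  })
}
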