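# Shared heavy runs, computed once per test session.

.run_cache <- new.env(parent = emptyenv())

# The scaled-down reference experiment: 400 + 100 LIF neurons, 3 s,
# ball-and-stick forward population. Used by the acceptance tests.
scaled_run <- function() {
  if (is.null(.run_cache$scaled)) {
    .run_cache$scaled <- run_experiment(scaled_config(seed = 42L))
  }
  .run_cache$scaled
}

# A small population traces object with smooth synthetic AMPA/GABA signals
synthetic_traces <- function(n = 5000, dt = 0.1, seed = 1) {
  withr::with_seed(seed, {
    smooth <- function(x, k) {
      as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
    }
    ampa <- smooth(rnorm(n + 200), 25)[101:(100 + n)]
    ampa <- ampa - min(ampa) + 0.5
    gaba <- -(smooth(rnorm(n + 200), 41)[101:(100 + n)]^2) - 0.2
    tibble::tibble(time = seq_len(n) * dt, population = "exc",
                   fr = rpois(n, 2), vm = smooth(rnorm(n + 200), 15)[101:(100 + n)],
                   ampa = ampa, gaba = gaba)
  })
}
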