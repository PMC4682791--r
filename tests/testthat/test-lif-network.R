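# Point-network stage: connectivity, external drives, integration accuracy.

test_that("connection counts follow the directed Bernoulli model", {
  # degenerate probabilities: exact edge counts
  net0 <- build_network(10, 5, p_dc = 0, seed = 1)
  expect_equal(sum(lengths(net0$adjacency)), 0L)
  net1 <- build_network(50, 50, p_dc = 1, seed = 1)
  expect_equal(sum(lengths(net1$adjacency)), 100L * 99L)
  net1s <- build_network(50, 50, p_dc = 1, seed = 1, allow_self = TRUE)
  expect_equal(sum(lengths(net1s$adjacency)), 100L * 100L)

  # realized density within 4 binomial standard deviations
  net <- build_network(80, 20, p_dc = 0.2, seed = 3)
  n_pairs <- 100 * 99
  edges <- sum(lengths(net$adjacency))
  expect_lt(abs(edges - 0.2 * n_pairs), 4 * sqrt(n_pairs * 0.2 * 0.8))

  # determinism
  net_b <- build_network(80, 20, p_dc = 0.2, seed = 3)
  expect_identical(net$adjacency, net_b$adjacency)
  expect_error(build_network(-5, 10), "non-negative")
})

test_that("OU drive has the stationary moments and autocorrelation of the process", {
  ou0 <- generate_ou_drive(16, 0, duration = 100, dt = 0.05, seed = 1)
  expect_true(all(ou0$value == 0))

  ou <- generate_ou_drive(16, 0.25, duration = 20000, dt = 0.05, seed = 7)
  # variance within 10% of sigma^2 for T >= 1000 tau_n
  expect_lt(abs(var(ou$value) / 0.25^2 - 1), 0.10)
  # long-run mean bound
  expect_lt(abs(mean(ou$value)), 3 * 0.25 / sqrt(20000 / 16))
  # lag-k autocorrelation ~ exp(-k dt / tau), absolute estimation error bound
  for (lag_ms in c(4, 16, 32)) {
    k <- lag_ms / 0.05
    emp <- cor(ou$value[-(1:k)], ou$value[1:(length(ou$value) - k)])
    expect_lt(abs(emp - exp(-lag_ms / 16)), 0.06)
  }
  expect_error(generate_ou_drive(16, 0.25, 100, dt = 20), "smaller")
})

test_that("Poisson train generators agree with the mean-count law and each other", {
  tr <- generate_poisson_trains(1.5, n_targets = 20, duration = 10000, seed = 5)
  counts <- tabulate(tr$neuron, 20)
  expect_lt(abs(mean(counts) - 15000), 4 * sqrt(15000 / 20))
  expect_true(all(diff(tr$time[tr$neuron == 1]) > 0))

  expect_equal(nrow(generate_poisson_trains(0, 5, duration = 1000, seed = 1)), 0L)

  # thinning vs per-bin Bernoulli on a time-varying rate: equal means
  rate <- rep(c(0.5, 2), each = 5000) * 0.6
  a <- generate_poisson_trains(rate, 50, dt = 0.1, seed = 2, method = "thinning")
  b <- generate_poisson_trains(rate, 50, dt = 0.1, seed = 3, method = "bernoulli")
  mu <- sum(rate * 0.1) * 50
  expect_lt(abs(nrow(a) - mu) / mu, 0.05)
  expect_lt(abs(nrow(b) - mu) / mu, 0.05)
})

test_that("single-neuron firing matches the closed-form LIF interspike interval", {
  net <- build_network(1, 0, p_dc = 0, seed = 1)
  for (drive in c(25, 40)) {
    sim <- simulate_lif(net, duration = 400, dt = 0.05, thalamic_rate = 0,
                        ou_sigma = 0, drive_mode = "current",
                        tonic_drive = drive, seed = 1)
    isi <- diff(sim$spikes$time)
    theory <- 2 + 20 * log((drive - 11) / (drive - 18))
    expect_true(all(abs(isi - theory) <= 0.05 + 1e-9))
  }
})

test_that("a quiescent neuron stays at rest", {
  net <- build_network(2, 1, p_dc = 0.5, seed = 1)
  sim <- simulate_lif(net, duration = 200, dt = 0.05, thalamic_rate = 0,
                      ou_sigma = 0, drive_mode = "current", seed = 1)
  expect_equal(nrow(sim$spikes), 0L)
  expect_true(all(abs(sim$traces$vm) < 1e-12))
})

test_that("absolute refractoriness bounds every interspike interval", {
  net <- build_network(30, 10, p_dc = 0.3, seed = 2)
  sim <- simulate_lif(net, duration = 1000, dt = 0.05, thalamic_rate = 2,
                      seed = 4)
  expect_gt(nrow(sim$spikes), 50)
  refr <- c(exc = 2, inh = 1)
  by_neuron <- split(sim$spikes$time, sim$spikes$neuron)
  pops <- ifelse(as.integer(names(by_neuron)) <= 30, "exc", "inh")
  min_isi <- vapply(by_neuron, function(t) if (length(t) > 1) min(diff(t)) else Inf,
                    numeric(1))
  expect_true(all(min_isi >= refr[pops] - 1e-9))
})

test_that("subthreshold dynamics are linear: drive responses superpose", {
  np <- lif_neuron_defaults()
  np$v_thr <- Inf  # disable spiking
  net <- build_network(3, 1, p_dc = 0.4, seed = 6)
  base <- list(network = net, duration = 300, dt = 0.05, ou_sigma = 0,
               drive_mode = "current", neuron_params = np, seed = 9)
  vm_syn <- do.call(simulate_lif, c(base, list(thalamic_rate = 1.0)))$traces$vm
  vm_ton <- do.call(simulate_lif, c(base, list(thalamic_rate = 0, tonic_drive = 5)))$traces$vm
  vm_both <- do.call(simulate_lif, c(base, list(thalamic_rate = 1.0, tonic_drive = 5)))$traces$vm
  expect_equal(vm_both, vm_syn + vm_ton, tolerance = 1e-10)
})

test_that("identical seeds give bit-identical simulations", {
  net <- build_network(20, 5, seed = 1)
  s1 <- simulate_lif(net, duration = 400, thalamic_rate = 1.5, seed = 11)
  s2 <- simulate_lif(net, duration = 400, thalamic_rate = 1.5, seed = 11)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$traces, s2$traces)
})

test_that("population signals respect the sign conventions and aggregation rules", {
  net <- build_network(30, 10, p_dc = 0.3, seed = 2)
  sim <- simulate_lif(net, duration = 800, thalamic_rate = 1.5, seed = 4)
  for (pop in c("exc", "inh", "all")) {
    tr <- population_signals(sim, pop, warmup = 100)
    expect_true(all(tr$ampa >= 0))
    expect_true(all(tr$gaba <= 0))
    expect_true(all(tr$fr >= 0 & tr$fr == round(tr$fr)))
    expect_true(all(tr$time > 100))
  }
  # 'all' sums currents and counts over both populations
  te <- population_signals(sim, "exc", warmup = 100)
  ti <- population_signals(sim, "inh", warmup = 100)
  ta <- population_signals(sim, "all", warmup = 100)
  expect_equal(ta$ampa, te$ampa + ti$ampa)
  expect_equal(ta$fr, te$fr + ti$fr)
  # resampling: counts are summed, currents averaged
  t2 <- population_signals(sim, "exc", warmup = 100, dt_out = 0.5)
  expect_equal(sum(t2$fr), sum(te$fr))
  expect_equal(mean(t2$ampa), mean(te$ampa), tolerance = 1e-6)
})
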