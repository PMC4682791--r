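# Passive cable stage: discretisation, input resistance, synapse placement
# and the implicit solver, cross-checked against independent ODE solutions.

pyr_passive <- function(set = "table") {
  pd <- passive_defaults(set)
  pd[pd$cell_type == "pyr", ]
}

test_that("an isopotential compartment has the closed-form input resistance", {
  bs <- ball_and_stick(0, 0, soma_diam = 20)
  mod <- discretize(bs, pyr_passive())
  expect_equal(mod$n_comp, 1L)
  r_theory <- 30000 / (pi * 20 * 20 * 1e-8) / 1e6  # R_m / area in MOhm
  expect_equal(input_resistance(mod), r_theory, tolerance = 1e-12)
})

test_that("the frequency-dependent length constant has the right DC limit and scaling", {
  lam <- lfpproxy:::lambda_f
  lam_dc <- sqrt((30000 / 150) * (1e-4 / 4)) * 1e4
  expect_equal(lam(1, 30000, 150, 1, f = 1e-9), lam_dc, tolerance = 1e-6)
  expect_lt(lam(1, 30000, 150, 1, f = 100), lam_dc)
  # halving the length cap at most doubles the compartment count of a cable
  bs <- ball_and_stick(0, 500, diam = 1)
  n1 <- discretize(bs, pyr_passive(), max_length = 80)$n_comp
  n2 <- discretize(bs, pyr_passive(), max_length = 40)$n_comp
  expect_lte(n2 - 1L, 2L * (n1 - 1L))
  expect_error(discretize(
    lfpproxy:::new_morph_tree(tibble::tibble(
      id = 1:2, parent = c(-1L, 1L), type = c(1L, 3L),
      x = 0, y = 0, z = c(0, -30), radius = c(5, 0))), pyr_passive()),
    "zero-diameter")
})

test_that("input resistance follows the 3/2-power diameter law toward the long-cable limit", {
  rin <- function(d) {
    bs <- ball_and_stick(0, 4000, diam = d, soma_diam = d)  # quasi-semi-infinite
    input_resistance(discretize(bs, pyr_passive(), max_length = 20))
  }
  # R_inf ~ d^(-3/2): doubling the diameter scales R by 2^(-1.5)
  expect_equal(rin(2) / rin(1), 2^-1.5, tolerance = 0.05)
})

test_that("synaptic waveforms are peak-normalised to the stated weight", {
  for (taus in list(c(0.4, 2), c(0.25, 5), c(0.2, 1))) {
    a <- lfpproxy:::biexp_norm(taus[1], taus[2])
    tt <- seq(0, 30, by = 1e-4)
    wave <- a * (exp(-tt / taus[2]) - exp(-tt / taus[1]))
    expect_equal(max(wave), 1, tolerance = 1e-3)
  }
})

test_that("the implicit solver matches an independent ODE integration on a chain", {
  skip_if_not_installed("deSolve")
  bs <- ball_and_stick(0, 150, diam = 2, soma_diam = 10)
  mod <- discretize(bs, pyr_passive(), max_length = 50)
  pop <- assemble_population(list(mod))
  n <- pop$n_comp
  expect_gte(n, 3L)
  tau_r <- 0.4; tau_d <- 2; w <- 0.07; t0 <- 2
  target <- n  # most distal compartment
  sm <- tibble::tibble(synapse = 1L, cell = 1L, comp = target, class = "ampa_rec",
                       source = "s", tau_r = tau_r, tau_d = tau_d,
                       weight = w, e_syn = 0, z = 0)
  ev <- tibble::tibble(source = "s", time = t0)
  res <- simulate_currents(pop, sm, ev, duration = 40, dt = 0.01,
                           record_vm = TRUE)
  # reference: stiff ODE solve of c dv/dt = -G v + I_syn(t)
  g <- as.matrix(Matrix::Diagonal(n, pop$g_l) + pop$lap)
  amp <- w * lfpproxy:::biexp_norm(tau_r, tau_d)
  rhs <- function(t, v, p) {
    i_syn <- numeric(n)
    if (t > t0) i_syn[target] <- amp * (exp(-(t - t0) / tau_d) - exp(-(t - t0) / tau_r))
    list((-g %*% v + i_syn) / pop$cap)
  }
  ref <- deSolve::lsoda(numeric(n), c(0, res$time), rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  v_ref <- ref[-1, 2]  # somatic voltage
  v_be <- res$vm_soma[1, ]
  expect_lt(sqrt(mean((v_be - v_ref)^2)) / sd(v_ref), 0.01)
})

test_that("transmembrane currents are conserved per cell to machine precision", {
  pop <- make_fixture("ball_stick_pop")
  sm <- place_synapses(pop, tibble::tibble(
    cell = rep(1:6, each = 3), source = paste0("s", 1:18),
    class = rep(c("ampa_rec", "ampa_th", "gaba"), 6)), mode = "REF", seed = 2)
  ev <- generate_poisson_trains(0.4, 18, duration = 80, seed = 3) |>
    dplyr::mutate(source = paste0("s", neuron)) |> dplyr::select(source, time)
  res <- simulate_currents(pop, sm, ev, duration = 80, dt = 0.1)
  percell <- rowsum(res$currents, pop$comps$cell)
  l1 <- colSums(abs(res$currents))
  active <- l1 > 0
  expect_lt(max(t(abs(percell[, active])) / l1[active]), 1e-6)
})

test_that("current-mode responses superpose over event streams", {
  pop <- make_fixture("ball_stick_pop")
  sm <- place_synapses(pop, tibble::tibble(
    cell = c(1L, 1L), source = c("a", "b"), class = c("ampa_rec", "gaba")),
    mode = "REF", seed = 4)
  run <- function(ev) simulate_currents(pop, sm, ev, duration = 40, dt = 0.1)$currents
  ia <- run(tibble::tibble(source = "a", time = c(3, 7)))
  ib <- run(tibble::tibble(source = "b", time = 11))
  iab <- run(tibble::tibble(source = c("a", "a", "b"), time = c(3, 7, 11)))
  expect_equal(iab, ia + ib, tolerance = 1e-12)
})

test_that("halving the time step barely changes somatic voltages", {
  bs <- ball_and_stick(100, 200, diam = 1)
  pop <- assemble_population(list(discretize(bs, pyr_passive(), max_length = 60)))
  sm <- tibble::tibble(synapse = 1L, cell = 1L, comp = pop$n_comp,
                       class = "ampa_rec", source = "s", tau_r = 0.4, tau_d = 2,
                       weight = 0.07, e_syn = 0, z = 0)
  ev <- tibble::tibble(source = "s", time = 5)
  v1 <- simulate_currents(pop, sm, ev, duration = 60, dt = 0.1, record_vm = TRUE)$vm_soma[1, ]
  v2 <- simulate_currents(pop, sm, ev, duration = 60, dt = 0.05, record_vm = TRUE)$vm_soma[1, ]
  v2 <- v2[seq(2, length(v2), by = 2)]
  expect_lt(sqrt(mean((v1 - v2)^2)) / sd(v1), 0.01)
})

test_that("conductance synapses at the resting reversal inject no net current", {
  bs <- ball_and_stick(100, 200, diam = 1)
  pop <- assemble_population(list(discretize(bs, pyr_passive(), max_length = 60)))
  sm <- tibble::tibble(synapse = 1L, cell = 1L, comp = 2L, class = "gaba",
                       source = "s", tau_r = 0.25, tau_d = 5, weight = 0.005,
                       e_syn = -70, z = 0)
  ev <- tibble::tibble(source = "s", time = 5)
  res <- simulate_currents(pop, sm, ev, mode = "conductance", duration = 40,
                           dt = 0.1, e_leak = -70, record_vm = TRUE)
  expect_lt(max(abs(res$vm_soma + 70)), 1e-9)
  expect_lt(max(abs(res$currents)), 1e-9)
})

test_that("synapse placement respects the mode regions and membrane-area weighting", {
  pop <- make_fixture("ball_stick_pop")
  # REF: GABA never above the cylinder junction
  presyn <- tibble::tibble(cell = rep(1:6, each = 10),
                           source = paste0("g", 1:60), class = "gaba")
  sm <- place_synapses(pop, presyn, mode = "REF", seed = 5)
  expect_true(all(sm$z <= 0 + 1e-9))
  # a cell entirely below the junction cannot host upper-only AMPA synapses
  low <- assemble_population(list(discretize(
    ball_and_stick(100, 50, soma_pos = c(0, 0, -200)), pyr_passive())))
  expect_error(
    place_synapses(low, tibble::tibble(cell = 1L, source = "a", class = "ampa_rec"),
                   mode = "AM_UP", seed = 1),
    "permitted")
  # area-proportional sampling within a cell (chi-squared goodness of fit)
  one <- assemble_population(list(discretize(
    ball_and_stick(150, 300, diam = 2, soma_pos = c(0, 0, -120)),
    pyr_passive(), max_length = 40)))
  many <- place_synapses(one, tibble::tibble(
    cell = 1L, source = paste0("s", 1:4000), class = "ampa_rec"),
    mode = "HOM", seed = 6)
  counts <- tabulate(many$comp, one$n_comp)
  p_area <- one$comps$area / sum(one$comps$area)
  expect_gt(stats::chisq.test(counts, p = p_area)$p.value, 0.01)
})
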