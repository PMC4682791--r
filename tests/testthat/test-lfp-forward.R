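# Line-source forward model: closed-form limits, quadrature oracle,
# superposition, and the dipole moment.

test_that("the point-source limit gives the closed-form potential", {
  # 1 nA at 100 um in a 0.3 S/m medium: I / (4 pi sigma r) = 2.653 uV
  phi <- line_source_potential(c(0, 0, 0), c(0, 0, 0), 1, c(100, 0, 0))
  expect_equal(phi, 1e3 / (4 * pi * 0.3 * 100), tolerance = 1e-6)
  expect_equal(phi, 2.6526, tolerance = 1e-4)
  expect_equal(line_source_potential(c(0, 0, -5), c(0, 0, 5), 0, c(50, 0, 0)), 0)
})

test_that("line-source potentials match numerical quadrature of the point-source kernel", {
  a <- c(0, 0, -15); b <- c(0, 0, 25)
  ds <- sqrt(sum((b - a)^2))
  for (el in list(c(40, 0, 0), c(10, 20, 60), c(0, 5, -80))) {
    num <- stats::integrate(function(s) {
      px <- a[1] + (b[1] - a[1]) * s / ds
      py <- a[2] + (b[2] - a[2]) * s / ds
      pz <- a[3] + (b[3] - a[3]) * s / ds
      1 / sqrt((el[1] - px)^2 + (el[2] - py)^2 + (el[3] - pz)^2)
    }, 0, ds, rel.tol = 1e-10)$value
    phi_num <- 1e3 * num / (4 * pi * 0.3 * ds)
    expect_equal(line_source_potential(a, b, 1, el), phi_num, tolerance = 1e-6)
  }
})

test_that("in the far field the line source collapses onto a midpoint monopole", {
  a <- c(0, 0, -5); b <- c(0, 0, 5)
  el <- c(1000, 0, 0)
  phi_line <- line_source_potential(a, b, 1, el)
  phi_point <- 1e3 / (4 * pi * 0.3 * 1000)
  expect_equal(phi_line, phi_point, tolerance = 0.01)
})

test_that("LFP superposes over cell-type subsets and vanishes for zero currents", {
  pop <- make_fixture("ball_stick_pop")
  n_t <- 50L
  withr::with_seed(8, {
    raw <- matrix(rnorm(pop$n_comp * n_t), pop$n_comp, n_t)
  })
  # enforce per-cell conservation so the inputs are physical
  for (cell in unique(pop$comps$cell)) {
    rows <- which(pop$comps$cell == cell)
    raw[rows, ] <- sweep(raw[rows, , drop = FALSE], 2,
                         colMeans(raw[rows, , drop = FALSE]))
  }
  cur <- structure(list(geometry = pop$comps, cells = pop$cells,
                        time = seq_len(n_t) * 0.1, dt = 0.1, mode = "current",
                        currents = raw, dipole = NULL, vm_soma = NULL,
                        subset = NULL),
                   class = "compartment_currents")
  el <- electrode_grid(z = seq(-300, 300, by = 100), x = 30)
  all <- compute_lfp(cur, el)
  pyr <- compute_lfp(cur, el, subset = "pyr")
  int <- compute_lfp(cur, el, subset = "int")
  expect_equal(all$lfp, pyr$lfp + int$lfp, tolerance = 1e-12)

  cur$currents[] <- 0
  expect_true(all(compute_lfp(cur, el)$lfp == 0))
})

test_that("two opposite monopoles give the textbook on-axis potential and far-field decay", {
  fx <- make_fixture("dipole")  # +-1 nA at z = +-50, pointlike segments
  el <- electrode_grid(z = c(150, 0, -150), x = 0.1)
  lfp <- suppressWarnings(compute_lfp(fx, el))
  two_mono <- function(z, x) {
    1e3 / (4 * pi * 0.3) * (1 / sqrt(x^2 + (z - 50)^2) - 1 / sqrt(x^2 + (z + 50)^2))
  }
  # segment length is 10 um here, so allow a small quadrature difference
  for (i in seq_len(3)) {
    expect_equal(lfp$lfp[i, 1], two_mono(el$z[i], el$x[i]), tolerance = 5e-3)
  }
  # antisymmetry about the dipole centre
  expect_equal(lfp$lfp[1, 1], -lfp$lfp[3, 1], tolerance = 1e-10)
  # pure-dipole far field: doubling the distance quarters the potential
  far <- electrode_grid(z = c(2000, 4000), x = 0)
  lfar <- suppressWarnings(compute_lfp(fx, far))
  expect_equal(lfar$lfp[1, 1] / lfar$lfp[2, 1], 4, tolerance = 0.02)
})

test_that("the dipole moment is the depth-weighted current sum", {
  fx <- make_fixture("dipole")
  dp <- dipole_moment(fx)
  expect_true(all(dp$dz == 100))  # (+1)(50) + (-1)(-50)
  expect_equal(dipole_amplitude(dp), 0)  # constant in time
  # symmetric arrangement: currents at equal depths cancel
  fx$geometry$zm <- c(50, 50)
  expect_true(all(dipole_moment(fx)$dz == 0))
})

test_that("population LFP decays weakly inside and steeply outside the column", {
  # 30 pyramidal sticks driven by one shared perisomatic source
  withr::with_seed(12, {
    trees <- lapply(1:30, function(i) {
      rho <- 250 * sqrt(runif(1)); phi <- runif(1, 0, 2 * pi)
      ball_and_stick(130, 250 - runif(1, -200, 0), diam = 0.55,
                     soma_diam = 5,
                     soma_pos = c(rho * cos(phi), rho * sin(phi), runif(1, -200, -20)))
    })
  })
  ps <- passive_defaults("table")[1, ]
  pop <- assemble_population(lapply(trees, discretize, passive = ps,
                                    max_length = 150))
  sm <- place_synapses(pop, tibble::tibble(
    cell = 1:30, source = "shared", class = "gaba"), mode = "REF",
    geometry = column_geometry(), seed = 3)
  sm$weight <- -0.145; sm$tau_r <- 0.25; sm$tau_d <- 5
  ev <- tibble::tibble(source = "shared",
                       time = sort(runif(120, 0, 400)))
  radii <- c(0, 125, 250, 500, 1000)
  el <- electrode_grid(z = -100, x = 1)  # placeholder, replaced below
  el <- tibble::tibble(electrode = seq_along(radii), x = radii, y = 0, z = -100)
  res <- simulate_currents(pop, sm, ev, duration = 400, dt = 0.1,
                           keep_currents = FALSE, electrodes = el)
  amp <- apply(res$lfp$lfp, 1, sd)
  # weak decay inside the population footprint (X/R <= 1) ...
  expect_gt(amp[2] / amp[1], 0.5)
  # ... steep decay outside it
  expect_lt(amp[5] / amp[3], 0.35)
  expect_true(all(diff(amp) < 0))
})
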