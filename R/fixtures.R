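# Deterministic toy objects for tests and examples.

#' Deterministic test fixtures
#'
#' Small, fully deterministic objects exercising each stage:
#' \describe{
#'   \item{`"lif3"`}{A 3-neuron network (2 excitatory driving 1 inhibitory)
#'     with a fixed adjacency, suitable for hand-checked simulations.}
#'   \item{`"swc5"`}{A 5-node branched morphology as a `morph_tree`.}
#'   \item{`"ball_stick_pop"`}{A ball-and-stick `cable_population` of 4
#'     pyramidal and 2 stellate-like cells.}
#'   \item{`"mixture"`}{Synthetic AMPA/GABA traces plus an `lfp` built as
#'     `AMPA(t - 6 ms) - 1.65 GABA(t)` with weak noise; the known
#'     parameters are attached as attribute `"truth"`.}
#'   \item{`"dipole"`}{A two-compartment `compartment_currents` object with
#'     equal and opposite 1 nA currents at z = +/- 50 um.}
#' }
#'
#' @param kind Fixture name.
#' @param seed Integer seed for the stochastic pieces.
#' @return The fixture object.
#' @export
make_fixture <- function(kind = c("lif3", "swc5", "ball_stick_pop", "mixture", "dipole"),
                         seed = 42L) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) abort(sprintf("unknown fixture kind '%s'", kind[1])))
  switch(kind,
    lif3 = {
      net <- build_network(2, 1, p_dc = 0, seed = 1L)
      net$adjacency <- list(3L, 3L, c(1L, 2L))  # e1 -> i3, e2 -> i3, i3 -> e1, e2
      net
    },
    swc5 = {
      nodes <- tibble(
        id = 1:5, parent = c(-1L, 1L, 2L, 2L, 1L),
        type = c(1L, 3L, 3L, 3L, 4L),
        x = c(0, 10, 30, 15, 0), y = c(0, 0, 0, 20, 0),
        z = c(0, -20, -40, -30, 60),
        radius = c(8, 1.5, 1, 1, 1.8)
      )
      new_morph_tree(nodes, "pyr")
    },
    ball_stick_pop = with_seed(seed, {
      trees <- c(
        lapply(1:4, function(i) {
          ball_and_stick(150, 300, diam = 2, soma_diam = 20,
                         soma_pos = c(runif(1, -50, 50), runif(1, -50, 50),
                                      runif(1, -200, -50)),
                         cell_type = "pyr")
        }),
        lapply(1:2, function(i) {
          ball_and_stick(80, 80, diam = 2, soma_diam = 15,
                         soma_pos = c(runif(1, -50, 50), runif(1, -50, 50),
                                      runif(1, -180, -100)),
                         cell_type = "int")
        })
      )
      passive <- passive_defaults("table")
      models <- lapply(trees, function(tr) {
        discretize(tr, passive[passive$cell_type == tr$cell_type, ],
                   max_length = 60)
      })
      assemble_population(models)
    }),
    mixture = with_seed(seed, {
      dt <- 0.1
      n <- 20000L
      t_ax <- seq_len(n) * dt
      # smooth correlated drivers: low-pass filtered noise
      smooth <- function(x, k) as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
      ampa <- smooth(rnorm(n + 200), 31)[101:(100 + n)]
      gaba <- -abs(smooth(rnorm(n + 200), 51)[101:(100 + n)]) - 0.5
      ampa <- ampa - min(ampa) + 0.1  # positive, like summed AMPA PSCs
      truth <- list(alpha = 1.65, tau_ampa = 6, tau_gaba = 0)
      ka <- round(truth$tau_ampa / dt)
      lfp <- c(rep(NA, ka), ampa[1:(n - ka)]) - truth$alpha * gaba
      lfp <- lfp + rnorm(n, 0, 0.02 * sd(lfp, na.rm = TRUE))
      keep <- !is.na(lfp)
      structure(
        list(traces = tibble(time = t_ax[keep], population = "exc",
                             fr = 0, vm = 0, ampa = ampa[keep], gaba = gaba[keep]),
             lfp = lfp[keep], dt = dt),
        truth = truth
      )
    }),
    dipole = {
      comps <- tibble(
        comp = 1:2, parent = c(0L, 1L),
        x0 = 0, y0 = 0, z0 = c(45, -55), x1 = 0, y1 = 0, z1 = c(55, -45),
        xm = 0, ym = 0, zm = c(50, -50), length = 10, diam = 2,
        area = pi * 2 * 10, type = c(4L, 3L), cell = 1L, cell_type = "pyr"
      )
      n_t <- 100L
      structure(
        list(geometry = comps,
             cells = tibble(cell = 1L, cell_type = "pyr", soma_comp = 1L),
             time = seq_len(n_t) * 0.1, dt = 0.1, mode = "current",
             currents = rbind(rep(1, n_t), rep(-1, n_t)),
             dipole = NULL, vm_soma = NULL, subset = NULL),
        class = "compartment_currents"
      )
    }
  )
}
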