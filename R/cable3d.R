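# Passive multicompartment stage: spatial discretisation by the
# frequency-dependent electrotonic length, synapse placement by membrane
# area within the mode-permitted depth regions, and replay of point-network
# synaptic event streams through bi-exponential synapses into an
# unconditionally stable backward-Euler cable solver.

# internal: frequency-dependent electrotonic length constant (um)
# lambda_f = lambda_DC / sqrt(0.5 (1 + sqrt(1 + (2 pi f R_m C_m)^2)))
lambda_f <- function(diam, r_m, r_a, c_m, f = 100) {
  lambda_dc <- sqrt((r_m / r_a) * (diam * 1e-4 / 4)) * 1e4  # um
  tau <- r_m * c_m * 1e-6  # s
  lambda_dc / sqrt(0.5 * (1 + sqrt(1 + (2 * pi * f * tau)^2)))
}

# internal: bi-exponential peak-normalisation factor so that
# A * (exp(-t_p/tau_d) - exp(-t_p/tau_r)) = 1 at the peak time t_p
biexp_norm <- function(tau_r, tau_d) {
  tp <- tau_d * tau_r / (tau_d - tau_r) * log(tau_d / tau_r)
  1 / (exp(-tp / tau_d) - exp(-tp / tau_r))
}

#' Discretise a morphology into a passive compartment model
#'
#' Each parent-child cable is split into compartments no longer than the
#' electrotonic length constant evaluated at `f_ref` (and never longer than
#' `max_length`). The soma node becomes a cylindrical compartment of length
#' equal to its diameter (sphere-matched lateral area). Electrical
#' parameters are derived from the specific constants and the compartment
#' geometry; internal units are um, nA, mV, ms (so conductances are uS and
#' capacitances nF).
#'
#' @param tree A `morph_tree`.
#' @param passive One row of [passive_defaults()] or a list with `r_m`
#'   (Ohm cm2), `r_a` (Ohm cm), `c_m` (uF/cm2).
#' @param f_ref Reference frequency (Hz) for the length rule.
#' @param max_length Optional hard cap on compartment length (um).
#' @return An object of class `cable_model`: compartment table (`comps` with
#'   end points, midpoint, length, diameter, area), axial conductances,
#'   per-compartment leak conductance `g_l` (uS) and capacitance `c` (nF).
#' @export
discretize <- function(tree, passive, f_ref = 100, max_length = Inf) {
  stopifnot(inherits(tree, "morph_tree"))
  if (is.data.frame(passive)) passive <- as.list(passive[1, ])
  nd <- tree$nodes
  if (any(nd$radius <= 0)) abort("zero-diameter segment in morphology")

  soma <- which(nd$parent <= 0)
  soma_d <- 2 * nd$radius[soma]
  comp <- list(tibble(
    parent = 0L,
    x0 = nd$x[soma], y0 = nd$y[soma], z0 = nd$z[soma] - soma_d / 2,
    x1 = nd$x[soma], y1 = nd$y[soma], z1 = nd$z[soma] + soma_d / 2,
    length = soma_d, diam = soma_d, type = 1L
  ))
  comp_of_node <- integer(nrow(nd))
  comp_of_node[soma] <- 1L
  n_comp <- 1L

  for (i in seq_len(nrow(nd))) {
    if (nd$parent[i] <= 0) next
    p <- match(nd$parent[i], nd$id)
    p0 <- c(nd$x[p], nd$y[p], nd$z[p])
    p1 <- c(nd$x[i], nd$y[i], nd$z[i])
    len <- sqrt(sum((p1 - p0)^2))
    if (len == 0) next
    # a dendrite leaving the soma keeps its own calibre: the soma radius
    # does not taper into the branch
    r_prox <- if (nd$type[p] == 1L) nd$radius[i] else nd$radius[p]
    dbar <- r_prox + nd$radius[i]
    lam <- lambda_f(dbar, passive$r_m, passive$r_a, passive$c_m, f_ref)
    nseg <- max(1L, ceiling(len / min(lam, max_length)))
    fr0 <- (seq_len(nseg) - 1) / nseg
    fr1 <- seq_len(nseg) / nseg
    frm <- (fr0 + fr1) / 2
    d_seg <- 2 * (r_prox + frm * (nd$radius[i] - r_prox))
    seg <- tibble(
      parent = c(comp_of_node[p], n_comp + seq_len(nseg - 1L)),
      x0 = p0[1] + fr0 * (p1[1] - p0[1]), y0 = p0[2] + fr0 * (p1[2] - p0[2]),
      z0 = p0[3] + fr0 * (p1[3] - p0[3]),
      x1 = p0[1] + fr1 * (p1[1] - p0[1]), y1 = p0[2] + fr1 * (p1[2] - p0[2]),
      z1 = p0[3] + fr1 * (p1[3] - p0[3]),
      length = len / nseg, diam = d_seg, type = nd$type[i]
    )
    comp <- c(comp, list(seg))
    n_comp <- n_comp + nseg
    comp_of_node[i] <- n_comp
  }
  comps <- bind_rows(comp)
  comps <- mutate(comps,
    comp = row_number(),
    xm = (.data$x0 + .data$x1) / 2, ym = (.data$y0 + .data$y1) / 2,
    zm = (.data$z0 + .data$z1) / 2,
    area = pi * .data$diam * .data$length
  )
  g_l <- comps$area * 1e-2 / passive$r_m        # uS
  cap <- passive$c_m * comps$area * 1e-5        # nF
  # axial conductance between compartment centres (uS)
  has_par <- comps$parent > 0L
  i <- comps$comp[has_par]; p <- comps$parent[has_par]
  r_half <- function(k) {
    passive$r_a * (comps$length[k] / 2) / (pi * (comps$diam[k] / 2)^2) * 1e-2  # MOhm
  }
  g_ax <- 1 / (r_half(i) + r_half(p))
  structure(
    list(comps = select(comps, "comp", "parent", "x0", "y0", "z0",
                        "x1", "y1", "z1", "xm", "ym", "zm",
                        "length", "diam", "area", "type"),
         g_l = g_l, cap = cap,
         edges = tibble(i = i, p = p, g = g_ax),
         passive = passive, cell_type = tree$cell_type,
         n_comp = nrow(comps)),
    class = "cable_model"
  )
}

#' @export
print.cable_model <- function(x, ...) {
  cat(sprintf("<cable_model> %s cell, %d compartments, total area %.0f um^2\n",
              x$cell_type, x$n_comp, sum(x$comps$area)))
  invisible(x)
}

# internal: axial Laplacian (uS), positive semidefinite, zero row sums
axial_laplacian <- function(edges, n) {
  if (nrow(edges) == 0L) return(Matrix::sparseMatrix(i = 1, j = 1, x = 0, dims = c(n, n)))
  Matrix::sparseMatrix(
    i = c(edges$i, edges$p, edges$i, edges$p),
    j = c(edges$i, edges$p, edges$p, edges$i),
    x = c(edges$g, edges$g, -edges$g, -edges$g),
    dims = c(n, n)
  )
}

#' Somatic input resistance of a passive compartment model
#'
#' Steady-state voltage response at the soma to a small constant somatic
#' current injection.
#'
#' @param model A `cable_model`.
#' @return Input resistance (MOhm).
#' @export
input_resistance <- function(model) {
  stopifnot(inherits(model, "cable_model"))
  g <- Matrix::Diagonal(model$n_comp, model$g_l) + axial_laplacian(model$edges, model$n_comp)
  rhs <- numeric(model$n_comp); rhs[1] <- 1  # 1 nA at the soma
  v <- Matrix::solve(g, rhs)
  as.numeric(v[1])  # mV per nA = MOhm
}

#' Assemble a population of compartment models into one system
#'
#' @param models List of `cable_model` objects.
#' @param cells Optional integer ids of the point-network counterparts (used
#'   to wire synaptic inputs); defaults to `seq_along(models)`.
#' @return A `cable_population`: stacked compartment table (with `cell` and
#'   `cell_type` columns), combined leak/capacitance vectors and a
#'   block-diagonal axial Laplacian.
#' @export
assemble_population <- function(models, cells = NULL) {
  if (is.null(cells)) cells <- seq_along(models)
  offs <- c(0L, cumsum(vapply(models, function(m) m$n_comp, integer(1))))
  comps <- purrr::map2_dfr(models, seq_along(models), function(m, k) {
    mutate(m$comps,
           comp = .data$comp + offs[k],
           parent = ifelse(.data$parent > 0L, .data$parent + offs[k], 0L),
           cell = cells[k], cell_type = m$cell_type)
  })
  edges <- purrr::map2_dfr(models, seq_along(models), function(m, k) {
    mutate(m$edges, i = .data$i + offs[k], p = .data$p + offs[k])
  })
  n <- nrow(comps)
  structure(
    list(comps = comps,
         g_l = unlist(lapply(models, `[[`, "g_l")),
         cap = unlist(lapply(models, `[[`, "cap")),
         edges = edges,
         lap = axial_laplacian(edges, n),
         soma = offs[seq_along(models)] + 1L,
         cells = tibble(cell = cells,
                        cell_type = vapply(models, `[[`, character(1), "cell_type"),
                        soma_comp = offs[seq_along(models)] + 1L),
         n_comp = n),
    class = "cable_population"
  )
}

#' @export
print.cable_population <- function(x, ...) {
  cat(sprintf("<cable_population> %d cells, %d compartments\n",
              nrow(x$cells), x$n_comp))
  invisible(x)
}

# internal: is a compartment midpoint inside the permitted depth region?
region_predicate <- function(region, geometry) {
  switch(region,
    everywhere = function(z) rep(TRUE, length(z)),
    lower = function(z) z <= geometry$lower[2] + 1e-9,
    upper = function(z) z >= geometry$upper[1] - 1e-9,
    abort(sprintf("unknown region '%s'", region))
  )
}

# internal: permitted region per synapse class under a distribution mode
mode_regions <- function(mode) {
  ampa <- switch(mode,
    HOM = "everywhere", REF = "everywhere",
    AM_UP = "upper", AM_DOWN = "lower", AMR_UP = "upper"
  )
  list(
    ampa_rec = ampa,
    ampa_cc = ampa,
    ampa_th = switch(mode, HOM = "everywhere", REF = "everywhere",
                     AM_UP = "upper", AM_DOWN = "lower", AMR_UP = "everywhere"),
    gaba = switch(mode, HOM = "everywhere", "lower")
  )
}

#' Place synapses on a compartment population
#'
#' Each presynaptic partner contributes a single synapse on its target cell,
#' placed on a compartment drawn with probability proportional to membrane
#' area within the depth region permitted for its synapse class under the
#' active distribution mode: `REF` (GABA in the lower cylinder only, AMPA
#' everywhere), `HOM` (all classes everywhere), `AM_UP` (AMPA upper only),
#' `AM_DOWN` (AMPA lower only), `AMR_UP` (recurrent/cortical AMPA upper,
#' thalamic AMPA everywhere).
#'
#' @param population A `cable_population`.
#' @param presyn Tibble with one row per synapse: `cell` (target cell id as
#'   in `population$cells$cell`), `source` (presynaptic stream label) and
#'   `class` (`ampa_rec`, `ampa_th`, `ampa_cc`, `gaba`).
#' @param mode Distribution mode, see Details.
#' @param geometry A [column_geometry()] defining the depth regions.
#' @param syn_params Synapse parameter table, see [syn3d_defaults()].
#' @param synapse_mode `"current"` (weights from `j`, nA) or `"conductance"`
#'   (weights from `g`, uS).
#' @param seed Integer seed.
#' @return A tibble (`synapse_map`) with columns `synapse`, `cell`, `comp`,
#'   `class`, `source`, `tau_r`, `tau_d`, `weight`, `e_syn`, `z`.
#' @export
place_synapses <- function(population, presyn, mode = c("REF", "HOM", "AM_UP", "AM_DOWN", "AMR_UP"),
                           geometry = column_geometry(),
                           syn_params = syn3d_defaults(),
                           synapse_mode = c("current", "conductance"),
                           seed = 1L) {
  mode <- match.arg(mode)
  synapse_mode <- match.arg(synapse_mode)
  stopifnot(inherits(population, "cable_population"))
  regions <- mode_regions(mode)
  comps <- population$comps
  cells <- population$cells
  sp <- as.data.frame(syn_params)

  with_seed(seed, {
    placed <- presyn %>%
      left_join(select(cells, "cell", "cell_type"), by = "cell") %>%
      group_by(.data$cell, .data$class) %>%
      dplyr::group_modify(function(df, key) {
        cc <- comps[comps$cell == key$cell, ]
        ok <- region_predicate(regions[[key$class]], geometry)(cc$zm)
        if (!any(ok)) {
          abort(sprintf(
            "no compartment of cell %d lies in the '%s' region permitted for %s synapses under mode %s",
            key$cell, regions[[key$class]], key$class, mode))
        }
        cc <- cc[ok, ]
        pick <- cc$comp[sample.int(nrow(cc), nrow(df), replace = TRUE, prob = cc$area)]
        mutate(df, comp = pick, z = cc$zm[match(pick, cc$comp)])
      }) %>%
      ungroup()
    pars <- sp[match(paste(placed$cell_type, placed$class),
                     paste(sp$cell_type, sp$class)), ]
    placed %>%
      mutate(
        synapse = row_number(),
        tau_r = pars$tau_r, tau_d = pars$tau_d,
        weight = if (synapse_mode == "current") pars$j else pars$g,
        e_syn = pars$e_syn
      ) %>%
      select("synapse", "cell", "comp", "class", "source",
             "tau_r", "tau_d", "weight", "e_syn", "z")
  })
}

#' Replay synaptic events into the passive population and record
#' transmembrane currents
#'
#' Advances the passive branched cable equations under bi-exponential
#' synaptic drive with the implicit (backward Euler) scheme, which is
#' unconditionally stable for this linear dissipative system. Synaptic
#' waveforms are peak-normalised: an isolated event produces a postsynaptic
#' current (or conductance) whose peak equals the synapse weight. The
#' per-compartment transmembrane current (capacitive + leak + synaptic) is
#' recovered from the axial currents, which makes per-cell current
#' conservation hold to machine precision — the property the forward model's
#' dipole structure rests on. No synaptic latency is applied at this stage.
#'
#' @param population A `cable_population`.
#' @param synapse_map Output of [place_synapses()].
#' @param events Tibble of presynaptic events with columns `source` and
#'   `time` (ms); every event triggers all synapses bound to that source.
#' @param mode `"current"` or `"conductance"`.
#' @param duration Simulated time (ms).
#' @param dt Time step (ms).
#' @param e_leak Leak reversal potential (mV, conductance mode; membrane
#'   potential is then absolute and initialised at `e_leak`).
#' @param keep_currents Keep the full compartment-by-time current matrix?
#'   Set `FALSE` (with `electrodes`) to stream directly into the forward
#'   model and save memory.
#' @param electrodes Optional [electrode_grid()]: the extracellular
#'   potential and dipole moment are then accumulated on the fly.
#' @param sigma Extracellular conductivity (S/m) for the streamed potential.
#' @param subset Optional cell-type filter (`"pyr"`, `"int"`) restricting
#'   which cells contribute to the streamed potential/dipole.
#' @param record_vm Record somatic membrane potentials?
#' @param chunk Steps per streaming block.
#' @return An object of class `compartment_currents` with the compartment
#'   geometry, the time axis, the current matrix (nA; if kept), streamed
#'   `lfp` / `dipole` results (if requested) and somatic voltages (if
#'   recorded).
#' @export
simulate_currents <- function(population, synapse_map, events,
                              mode = c("current", "conductance"),
                              duration, dt = 0.1, e_leak = -70,
                              keep_currents = TRUE,
                              electrodes = NULL, sigma = 0.3, subset = NULL,
                              record_vm = FALSE, chunk = 2000L) {
  mode <- match.arg(mode)
  stopifnot(inherits(population, "cable_population"))
  if (dt > 0.1 + 1e-12) warn("`dt` above 0.1 ms for the cable stage")
  n <- population$n_comp
  n_steps <- round(duration / dt)

  # channels: synapses sharing compartment and kinetics collapse into one
  # linear filter state (valid because the waveform itself is input-driven)
  sm <- synapse_map
  key <- paste(sm$comp, sm$tau_r, sm$tau_d, sm$weight, sm$e_syn)
  chan_of_syn <- match(key, unique(key))
  chan <- sm[!duplicated(key), c("comp", "tau_r", "tau_d", "weight", "e_syn")]
  n_chan <- nrow(chan)
  amp <- chan$weight * biexp_norm(chan$tau_r, chan$tau_d)
  dec_d <- exp(-dt / chan$tau_d)
  dec_r <- exp(-dt / chan$tau_r)
  tmat <- Matrix::sparseMatrix(i = chan$comp, j = seq_len(n_chan), x = 1,
                               dims = c(n, n_chan))

  # expand events to channel jumps
  syn_by_source <- split(chan_of_syn, sm$source)
  src_idx <- match(as.character(events$source), names(syn_by_source))
  if (anyNA(src_idx)) {
    events <- events[!is.na(src_idx), ]
    src_idx <- src_idx[!is.na(src_idx)]
  }
  hit <- syn_by_source[src_idx]
  ev_chan <- unlist(hit, use.names = FALSE) %||% integer(0)
  ev_step <- rep.int(pmin(pmax(floor(events$time / dt) + 1L, 1L), n_steps),
                     lengths(hit))
  ev <- aggregate_events(ev_step, ev_chan, n_steps)

  lap <- population$lap
  g_l <- population$g_l
  cap <- population$cap
  m0 <- Matrix::Diagonal(n, cap / dt + g_l) + lap
  # cells are mutually uncoupled, so the system matrix is block-diagonal and
  # its inverse stays sparse: one matvec per step replaces a factor solve
  minv <- if (mode == "current") Matrix::solve(m0) else NULL

  v <- if (mode == "current") numeric(n) else rep(e_leak, n)
  hd <- numeric(n_chan); hr <- numeric(n_chan)

  keep <- isTRUE(keep_currents)
  currents <- if (keep) matrix(0, n, n_steps) else NULL
  stream <- !is.null(electrodes)
  if (stream) {
    sel <- if (is.null(subset)) seq_len(n) else {
      which(population$comps$cell_type %in% subset)
    }
    mls <- ls_potential_matrix(population$comps[sel, ], electrodes, sigma)
    lfp_mat <- matrix(0, nrow(electrodes), n_steps)
    zm_sel <- population$comps$zm[sel]
  }
  dipole <- numeric(n_steps)
  if (!stream) {
    sel <- seq_len(n); zm_sel <- population$comps$zm
  }
  vm_soma <- if (record_vm) matrix(0, nrow(population$cells), n_steps) else NULL

  i_chunk <- matrix(0, n, min(chunk, n_steps))
  col <- 0L
  flush_from <- 1L
  for (step in seq_len(n_steps)) {
    hd <- hd * dec_d
    hr <- hr * dec_r
    a <- ev$ptr[step] + 1L; b <- ev$ptr[step + 1L]
    if (b >= a) {
      id <- ev$neuron[a:b]; cnt <- ev$count[a:b]
      hd[id] <- hd[id] + cnt
      hr[id] <- hr[id] + cnt
    }
    wave <- hd - hr
    if (mode == "current") {
      i_syn <- as.numeric(tmat %*% (amp * wave))
      rhs <- (cap / dt) * v + i_syn
      v <- as.numeric(minv %*% rhs)
    } else {
      g_syn <- amp * wave
      gs <- as.numeric(tmat %*% g_syn)
      ge <- as.numeric(tmat %*% (g_syn * chan$e_syn))
      a_t <- m0 + Matrix::Diagonal(n, gs)
      rhs <- (cap / dt) * v + g_l * e_leak + ge
      v <- as.numeric(Matrix::solve(a_t, rhs))
    }
    # divergence guard: current-based membranes are free to carry a large
    # (linear, harmless) DC offset, so the bound is generous; conductance
    # mode is confined between the reversal potentials
    v_cap <- if (mode == "current") 1e4 else 500 + abs(e_leak)
    if (max(abs(v)) > v_cap) {
      abort("cable solver instability detected: voltage out of bounds")
    }
    im <- -as.numeric(lap %*% v)
    col <- col + 1L
    i_chunk[, col] <- im
    if (record_vm) vm_soma[, step] <- v[population$cells$soma_comp]
    if (col == ncol(i_chunk) || step == n_steps) {
      cols_used <- seq_len(col)
      block <- i_chunk[, cols_used, drop = FALSE]
      rng <- flush_from:step
      if (keep) currents[, rng] <- block
      if (stream) lfp_mat[, rng] <- as.matrix(mls %*% block[sel, , drop = FALSE])
      dipole[rng] <- as.numeric(zm_sel %*% block[sel, , drop = FALSE])
      flush_from <- step + 1L
      col <- 0L
    }
  }

  time_axis <- seq_len(n_steps) * dt
  out <- structure(
    list(geometry = population$comps, cells = population$cells,
         time = time_axis, dt = dt, mode = mode,
         currents = currents,
         dipole = tibble(time = time_axis, dz = dipole),
         vm_soma = vm_soma,
         subset = subset),
    class = "compartment_currents"
  )
  if (stream) {
    out$lfp <- new_lfp_array(lfp_mat, electrodes, time_axis, subset, sigma)
  }
  out
}

#' @export
print.compartment_currents <- function(x, ...) {
  cat(sprintf("<compartment_currents> %d compartments x %d steps (dt = %g ms, %s synapses)\n",
              nrow(x$geometry), length(x$time), x$dt, x$mode))
  invisible(x)
}
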