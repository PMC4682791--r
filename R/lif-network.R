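#' Build a random sparse directed network
#'
#' Every ordered pair of neurons is connected independently with probability
#' `p_dc`. Neurons `1..n_exc` are excitatory, the remaining `n_inh` are
#' inhibitory. Self-connections are excluded by default.
#'
#' @param n_exc,n_inh Population sizes.
#' @param p_dc Directed connection probability.
#' @param seed Integer seed; the same seed yields the identical network.
#' @param allow_self Allow self-connections?
#' @return An object of class `lif_network` with fields `n_exc`, `n_inh`,
#'   `p_dc`, `seed` and `adjacency` (a list of postsynaptic target indices,
#'   one entry per presynaptic neuron).
#' @export
#' @examples
#' net <- build_network(40, 10, p_dc = 0.2, seed = 1)
#' mean(lengths(net$adjacency))  # mean out-degree, about 0.2 * 50
build_network <- function(n_exc, n_inh, p_dc = 0.2, seed = 1L, allow_self = FALSE) {
  if (n_exc < 0 || n_inh < 0 || n_exc + n_inh < 1) {
    abort("population sizes must be non-negative with at least one neuron")
  }
  if (p_dc < 0 || p_dc > 1) abort("`p_dc` must lie in [0, 1]")
  n <- as.integer(n_exc + n_inh)
  adjacency <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      tgt <- if (p_dc >= 1) seq_len(n) else which(runif(n) < p_dc)
      if (!allow_self) tgt <- tgt[tgt != i]
      as.integer(tgt)
    })
  })
  structure(
    list(n_exc = as.integer(n_exc), n_inh = as.integer(n_inh), p_dc = p_dc,
         seed = as.integer(seed), allow_self = allow_self, adjacency = adjacency),
    class = "lif_network"
  )
}

#' @export
print.lif_network <- function(x, ...) {
  cat(sprintf(
    "<lif_network> %d excitatory + %d inhibitory neurons, p = %g, %d edges\n",
    x$n_exc, x$n_inh, x$p_dc, sum(lengths(x$adjacency))
  ))
  invisible(x)
}

#' Edge list of a network
#'
#' @param network A `lif_network`.
#' @return A tibble with columns `from`, `to` and the presynaptic population
#'   label `from_pop`.
#' @export
network_edges <- function(network) {
  stopifnot(inherits(network, "lif_network"))
  from <- rep.int(seq_along(network$adjacency), lengths(network$adjacency))
  tibble(
    from = from,
    to = unlist(network$adjacency, use.names = FALSE) %||% integer(0),
    from_pop = ifelse(from <= network$n_exc, "exc", "inh")
  )
}

#' Ornstein-Uhlenbeck drive trace
#'
#' Zero-mean OU process `tau_n dOU = -OU dt + sigma sqrt(2 tau_n) dW`
#' sampled exactly on the simulation grid (stationary variance `sigma^2`,
#' autocorrelation time `tau_n`). The process is initialised from its
#' stationary distribution.
#'
#' @param ou_tau Correlation time constant tau_n (ms).
#' @param ou_sigma Stationary standard deviation (mV).
#' @param duration Trace duration (ms).
#' @param dt Time step (ms); must be smaller than `ou_tau`.
#' @param seed Integer seed.
#' @return A tibble with columns `time` (ms, grid `dt, 2 dt, ...`) and `value`.
#' @export
generate_ou_drive <- function(ou_tau = 16, ou_sigma = 0.25, duration = 10100,
                              dt = 0.05, seed = 1L) {
  check_positive(ou_tau, "ou_tau")
  check_nonnegative(ou_sigma, "ou_sigma")
  check_positive(duration, "duration")
  check_positive(dt, "dt")
  if (dt >= ou_tau) abort("`dt` must be smaller than `ou_tau`")
  n <- round(duration / dt)
  a <- exp(-dt / ou_tau)
  b <- ou_sigma * sqrt(1 - a^2)
  value <- with_seed(seed, {
    x0 <- rnorm(1L, 0, ou_sigma)
    innov <- b * rnorm(n)
    as.numeric(stats::filter(innov, a, method = "recursive", init = x0))
  })
  tibble(time = seq_len(n) * dt, value = value)
}

#' Poisson spike trains with a common (possibly time-varying) rate
#'
#' Generates `n_targets` independent Poisson processes sharing the same rate.
#' A scalar rate gives homogeneous trains over `[0, duration]`; a per-step
#' rate trace (spikes/ms, one value per `dt` bin) gives inhomogeneous trains,
#' realised either by thinning a homogeneous process at the maximal rate
#' (default) or by per-bin Bernoulli draws.
#'
#' @param rate Scalar rate (spikes/ms) or numeric vector of per-step rates.
#'   Negative values are clipped to zero.
#' @param n_targets Number of independent trains.
#' @param dt Time step used to interpret a vector `rate` (ms).
#' @param duration Duration (ms); required for scalar `rate`, otherwise
#'   inferred as `length(rate) * dt`.
#' @param seed Integer seed.
#' @param method `"thinning"` or `"bernoulli"` (vector rates only).
#' @return A tibble of spike events with columns `neuron` (1..n_targets) and
#'   `time` (ms), sorted by neuron then time.
#' @export
generate_poisson_trains <- function(rate, n_targets, dt = 0.05, duration = NULL,
                                    seed = 1L, method = c("thinning", "bernoulli")) {
  method <- match.arg(method)
  rate <- pmax(rate, 0)
  if (n_targets < 1) abort("`n_targets` must be at least 1")
  with_seed(seed, {
    if (length(rate) == 1L) {
      if (is.null(duration)) abort("`duration` is required for a scalar rate")
      counts <- rpois(n_targets, rate * duration)
      neuron <- rep.int(seq_len(n_targets), counts)
      time <- runif(sum(counts), 0, duration)
    } else {
      n_steps <- length(rate)
      duration <- n_steps * dt
      if (method == "thinning") {
        rmax <- max(rate)
        if (rmax == 0) {
          neuron <- integer(0); time <- numeric(0)
        } else {
          counts <- rpois(n_targets, rmax * duration)
          neuron <- rep.int(seq_len(n_targets), counts)
          time <- runif(sum(counts), 0, duration)
          bin <- pmin(pmax(ceiling(time / dt), 1L), n_steps)
          keep <- runif(length(time)) < rate[bin] / rmax
          neuron <- neuron[keep]; time <- time[keep]
        }
      } else {
        p <- pmin(rate * dt, 1)
        hits <- which(matrix(runif(n_steps * n_targets), n_steps, n_targets) <
                        p)  # column-major: step index + neuron index
        step <- (hits - 1L) %% n_steps + 1L
        neuron <- (hits - 1L) %/% n_steps + 1L
        time <- step * dt
      }
    }
    ord <- order(neuron, time)
    tibble(neuron = neuron[ord], time = time[ord])
  })
}

# internal: aggregate event (step, neuron) pairs into a per-step CSR-like
# structure with unique neurons and counts, for O(1) per-step consumption
aggregate_events <- function(step, neuron, n_steps) {
  keep <- step >= 1L & step <= n_steps
  step <- step[keep]; neuron <- neuron[keep]
  if (length(step) == 0L) {
    return(list(ptr = integer(n_steps + 1L), neuron = integer(0), count = integer(0)))
  }
  key <- (as.double(step) - 1) * (max(neuron) + 1) + neuron
  ord <- order(key)
  key <- key[ord]; step <- step[ord]; neuron <- neuron[ord]
  new <- c(TRUE, key[-1L] != key[-length(key)])
  idx <- which(new)
  count <- diff(c(idx, length(key) + 1L))
  step_u <- step[idx]; neuron_u <- neuron[idx]
  per_step <- tabulate(step_u, n_steps)
  list(ptr = c(0L, cumsum(per_step)), neuron = neuron_u, count = count)
}

# internal: exact one-step propagator for the linear (V, PSC_k, x_k) system
# of one population; state columns are (V, P1, x1, ..., P4, x4)
lif_propagator <- function(tau_m, tau_d, tau_r, dt) {
  k <- length(tau_d)
  m <- 1L + 2L * k
  a <- matrix(0, m, m)
  a[1, 1] <- -1 / tau_m
  for (j in seq_len(k)) {
    pj <- 2L * j; xj <- 2L * j + 1L
    a[1, pj] <- 1 / tau_m
    a[pj, pj] <- -1 / tau_d[j]
    a[pj, xj] <- 1 / tau_d[j]
    a[xj, xj] <- -1 / tau_r[j]
  }
  as.matrix(Matrix::expm(Matrix::Matrix(a * dt)))
}

#' Simulate the recurrent LIF network
#'
#' Integrates the subthreshold dynamics
#' \deqn{\tau_m \dot V = -V + \sum PSC(t) (+ D)}
#' with current-based bi-exponential synapses driven by recurrent spikes
#' (conduction delay `latency`), per-neuron thalamic Poisson trains at a
#' constant rate, and a shared slow cortico-cortical drive derived from an
#' Ornstein-Uhlenbeck process. The linear state (membrane potential plus the
#' four synapse-class filters) is advanced with the exact matrix-exponential
#' update per time step, so subthreshold trajectories carry no integration
#' error; threshold crossings are registered on the grid at the end of the
#' step in which they occur, the potential is reset and held for the absolute
#' refractory period.
#'
#' The cortico-cortical OU drive couples in one of two ways: as a
#' rate-modulated Poisson train through the cc AMPA synapse
#' (`drive_mode = "rate"`, the default), with rate
#' `nu(t) = nu0 + OU(t) / (tau_m J_cc)` of the excitatory population
#' (clipped at zero) so that the quasi-static voltage-equivalent fluctuation
#' matches `ou_sigma`; or directly as a voltage forcing in the membrane
#' equation (`drive_mode = "current"`).
#'
#' @param network A `lif_network`.
#' @param duration Simulated time (ms).
#' @param dt Time step (ms).
#' @param thalamic_rate Constant thalamic input rate (spikes/ms) per neuron.
#' @param ou_tau,ou_sigma OU drive parameters (ms, mV).
#' @param drive_mode `"rate"` or `"current"` (see Details).
#' @param cc_baseline Baseline cortico-cortical rate (spikes/ms) in rate mode;
#'   default is the rate whose voltage equivalent is `3 * ou_sigma`.
#' @param tonic_drive Constant voltage-target forcing D (mV), scalar or named
#'   `c(exc =, inh =)`; useful for controlled single-neuron protocols.
#' @param neuron_params,synapse_params Parameter tibbles in the format of
#'   [lif_neuron_defaults()] and [lif_synapse_defaults()].
#' @param record_neurons Integer neuron indices whose membrane potential and
#'   per-class synaptic currents are recorded at full resolution.
#' @param v_bound Sanity bound (mV); the run aborts if any |V| exceeds it.
#' @param seed Integer seed controlling all randomness of the run.
#' @return An object of class `lif_sim`: a list with `spikes` (tibble
#'   `neuron`, `time`, `population`), `traces` (per-population, per-step
#'   firing-rate counts, mean membrane potential and summed AMPA/GABA
#'   postsynaptic currents), `external` (the realised thalamic and
#'   cortico-cortical input events, for replay into the forward model),
#'   `recorded` (per-neuron traces, if requested) and the run configuration.
#' @export
simulate_lif <- function(network, duration = 10100, dt = 0.05,
                         thalamic_rate = 1.5,
                         ou_tau = 16, ou_sigma = 0.25,
                         drive_mode = c("rate", "current"),
                         cc_baseline = NULL,
                         tonic_drive = 0,
                         neuron_params = lif_neuron_defaults(),
                         synapse_params = lif_synapse_defaults(),
                         latency = 1,
                         record_neurons = integer(0),
                         v_bound = 1000,
                         seed = 1L) {
  stopifnot(inherits(network, "lif_network"))
  drive_mode <- match.arg(drive_mode)
  check_positive(duration, "duration")
  check_positive(dt, "dt")
  if (dt > 0.05 + 1e-12) {
    warn("`dt` above 0.05 ms: spike timing resolution is reduced")
  }
  n_e <- network$n_exc; n_i <- network$n_inh; n <- n_e + n_i
  n_steps <- round(duration / dt)
  delay_steps <- max(1L, as.integer(round(latency / dt)))
  classes <- c("ampa_rec", "ampa_th", "ampa_cc", "gaba")

  np <- as.data.frame(neuron_params)
  sp <- as.data.frame(synapse_params)
  pop_par <- lapply(c("exc", "inh"), function(p) {
    r <- np[np$population == p, ]
    s <- sp[sp$population == p, ]
    s <- s[match(classes, s$class), ]
    list(tau_m = r$tau_m, v_thr = r$v_thr, v_reset = r$v_reset,
         refr_steps = as.integer(round(r$tau_refr / dt)),
         tau_r = s$tau_r, tau_d = s$tau_d, j = s$j)
  })
  names(pop_par) <- c("exc", "inh")

  if (length(tonic_drive) == 1L) tonic_drive <- c(exc = tonic_drive, inh = tonic_drive)

  seeds <- with_seed(seed, sample.int(2^31 - 2, 4L))

  # external input event streams (shared rates, independent realisations)
  ou <- generate_ou_drive(ou_tau, ou_sigma, duration, dt, seed = seeds[1])
  thal <- if (thalamic_rate > 0) {
    generate_poisson_trains(thalamic_rate, n, dt, duration, seed = seeds[2])
  } else {
    tibble(neuron = integer(0), time = numeric(0))
  }
  cc_rate <- NULL
  if (drive_mode == "rate") {
    conv <- pop_par$exc$tau_m * pop_par$exc$j[3]  # mV per (spike/ms)
    if (is.null(cc_baseline)) cc_baseline <- 3 * ou_sigma / conv
    cc_rate <- pmax(0, cc_baseline + ou$value / conv)
    cc <- generate_poisson_trains(cc_rate, n, dt, seed = seeds[3])
  } else {
    cc <- tibble(neuron = integer(0), time = numeric(0))
  }

  ev_th <- aggregate_events(pmin(pmax(ceiling(thal$time / dt), 1L), n_steps),
                            thal$neuron, n_steps)
  ev_cc <- aggregate_events(pmin(pmax(ceiling(cc$time / dt), 1L), n_steps),
                            cc$neuron, n_steps)

  # per-population propagators and spike-arrival increments dx = tau_m J / tau_r
  phi_t <- lapply(pop_par, function(p) t(lif_propagator(p$tau_m, p$tau_d, p$tau_r, dt)))
  dx <- lapply(pop_par, function(p) p$tau_m * p$j / p$tau_r)
  idx_e <- seq_len(n_e); idx_i <- n_e + seq_len(n_i)
  pop_of <- rep(1:2, c(n_e, n_i))

  s_e <- matrix(0, n_e, 9L); s_i <- matrix(0, n_i, 9L)
  refr <- integer(n)
  adj <- network$adjacency

  fr_e <- integer(n_steps); fr_i <- integer(n_steps)
  vm_e <- numeric(n_steps); vm_i <- numeric(n_steps)
  ampa_e <- numeric(n_steps); ampa_i <- numeric(n_steps)
  gaba_e <- numeric(n_steps); gaba_i <- numeric(n_steps)
  spike_steps <- vector("list", n_steps)
  rec_idx <- as.integer(record_neurons)
  record <- length(rec_idx) > 0L
  if (record) {
    rec_vm <- matrix(0, length(rec_idx), n_steps)
    rec_ampa <- matrix(0, length(rec_idx), n_steps)
    rec_gaba <- matrix(0, length(rec_idx), n_steps)
  }

  decay_e <- 1 - exp(-dt / pop_par$exc$tau_m)
  decay_i <- 1 - exp(-dt / pop_par$inh$tau_m)
  p_cols <- c(2L, 4L, 6L)
  ring <- vector("list", delay_steps)
  pos <- 1L

  for (step in seq_len(n_steps)) {
    s_e <- s_e %*% phi_t$exc
    s_i <- s_i %*% phi_t$inh

    # external synaptic events
    a <- ev_th$ptr[step] + 1L; b <- ev_th$ptr[step + 1L]
    if (b >= a) {
      ids <- ev_th$neuron[a:b]; cnt <- ev_th$count[a:b]
      ee <- ids <= n_e
      if (any(ee)) s_e[ids[ee], 5L] <- s_e[ids[ee], 5L] + dx$exc[2] * cnt[ee]
      if (any(!ee)) s_i[ids[!ee] - n_e, 5L] <- s_i[ids[!ee] - n_e, 5L] + dx$inh[2] * cnt[!ee]
    }
    a <- ev_cc$ptr[step] + 1L; b <- ev_cc$ptr[step + 1L]
    if (b >= a) {
      ids <- ev_cc$neuron[a:b]; cnt <- ev_cc$count[a:b]
      ee <- ids <= n_e
      if (any(ee)) s_e[ids[ee], 7L] <- s_e[ids[ee], 7L] + dx$exc[3] * cnt[ee]
      if (any(!ee)) s_i[ids[!ee] - n_e, 7L] <- s_i[ids[!ee] - n_e, 7L] + dx$inh[3] * cnt[!ee]
    }

    # recurrent arrivals delayed by `latency`
    arr <- ring[[pos]]
    if (!is.null(arr) && length(arr)) {
      src_e <- arr[arr <= n_e]
      if (length(src_e)) {
        tgt <- unlist(adj[src_e], use.names = FALSE)
        if (length(tgt)) {
          cnt <- tabulate(tgt, n)
          hit <- which(cnt > 0L)
          he <- hit[hit <= n_e]; hi <- hit[hit > n_e]
          if (length(he)) s_e[he, 3L] <- s_e[he, 3L] + dx$exc[1] * cnt[he]
          if (length(hi)) s_i[hi - n_e, 3L] <- s_i[hi - n_e, 3L] + dx$inh[1] * cnt[hi]
        }
      }
      src_i <- arr[arr > n_e]
      if (length(src_i)) {
        tgt <- unlist(adj[src_i], use.names = FALSE)
        if (length(tgt)) {
          cnt <- tabulate(tgt, n)
          hit <- which(cnt > 0L)
          he <- hit[hit <= n_e]; hi <- hit[hit > n_e]
          if (length(he)) s_e[he, 9L] <- s_e[he, 9L] + dx$exc[4] * cnt[he]
          if (length(hi)) s_i[hi - n_e, 9L] <- s_i[hi - n_e, 9L] + dx$inh[4] * cnt[hi]
        }
      }
    }

    # non-synaptic voltage forcing (tonic and, in current mode, the OU drive)
    d_e <- tonic_drive[["exc"]]
    d_i <- tonic_drive[["inh"]]
    if (drive_mode == "current") {
      d_e <- d_e + ou$value[step]
      d_i <- d_i + ou$value[step]
    }
    if (d_e != 0) s_e[, 1L] <- s_e[, 1L] + decay_e * d_e
    if (d_i != 0) s_i[, 1L] <- s_i[, 1L] + decay_i * d_i

    # refractory clamp
    rf <- which(refr > 0L)
    if (length(rf)) {
      rfe <- rf[rf <= n_e]; rfi <- rf[rf > n_e]
      if (length(rfe)) s_e[rfe, 1L] <- pop_par$exc$v_reset
      if (length(rfi)) s_i[rfi - n_e, 1L] <- pop_par$inh$v_reset
      refr[rf] <- refr[rf] - 1L
    }

    # threshold crossing, reset, refractory onset
    sp_e <- which(s_e[, 1L] > pop_par$exc$v_thr & refr[idx_e] == 0L)
    sp_i <- which(s_i[, 1L] > pop_par$inh$v_thr & refr[idx_i] == 0L)
    if (length(sp_e)) {
      s_e[sp_e, 1L] <- pop_par$exc$v_reset
      refr[sp_e] <- pop_par$exc$refr_steps
    }
    if (length(sp_i)) {
      s_i[sp_i, 1L] <- pop_par$inh$v_reset
      refr[n_e + sp_i] <- pop_par$inh$refr_steps
    }
    spikers <- c(sp_e, n_e + sp_i)
    if (length(spikers)) spike_steps[[step]] <- spikers
    ring[[pos]] <- spikers
    pos <- if (pos == delay_steps) 1L else pos + 1L

    cs_e <- .colSums(s_e, n_e, 9L)
    cs_i <- .colSums(s_i, n_i, 9L)
    fr_e[step] <- length(sp_e); fr_i[step] <- length(sp_i)
    vm_e[step] <- cs_e[1L] / n_e; vm_i[step] <- cs_i[1L] / n_i
    ampa_e[step] <- sum(cs_e[p_cols]); ampa_i[step] <- sum(cs_i[p_cols])
    gaba_e[step] <- cs_e[8L]; gaba_i[step] <- cs_i[8L]

    if (record) {
      for (r in seq_along(rec_idx)) {
        id <- rec_idx[r]
        row <- if (id <= n_e) s_e[id, ] else s_i[id - n_e, ]
        rec_vm[r, step] <- row[1L]
        rec_ampa[r, step] <- sum(row[p_cols])
        rec_gaba[r, step] <- row[8L]
      }
    }

    if (step %% 2000L == 0L &&
        (max(abs(s_e[, 1L])) > v_bound || (n_i > 0 && max(abs(s_i[, 1L])) > v_bound))) {
      abort("simulation diverged: membrane potential exceeded the sanity bound")
    }
  }

  n_spk <- lengths(spike_steps)
  spike_neuron <- unlist(spike_steps, use.names = FALSE) %||% integer(0)
  spike_time <- rep.int(seq_len(n_steps), n_spk) * dt
  ord <- order(spike_neuron, spike_time)
  spikes <- tibble(
    neuron = spike_neuron[ord],
    time = spike_time[ord],
    population = ifelse(spike_neuron[ord] <= n_e, "exc", "inh")
  )

  time_axis <- seq_len(n_steps) * dt
  traces <- bind_rows(
    tibble(time = time_axis, population = "exc", fr = fr_e, vm = vm_e,
           ampa = ampa_e, gaba = gaba_e),
    tibble(time = time_axis, population = "inh", fr = fr_i, vm = vm_i,
           ampa = ampa_i, gaba = gaba_i)
  )

  recorded <- NULL
  if (record) {
    recorded <- list(neuron = rec_idx, time = time_axis,
                     vm = rec_vm, ampa = rec_ampa, gaba = rec_gaba)
  }

  structure(
    list(
      spikes = spikes, traces = traces,
      external = list(thalamic = thal, cortical = cc, ou = ou, cc_rate = cc_rate),
      recorded = recorded,
      network = network,
      config = list(duration = duration, dt = dt, thalamic_rate = thalamic_rate,
                    ou_tau = ou_tau, ou_sigma = ou_sigma, drive_mode = drive_mode,
                    cc_baseline = cc_baseline, latency = latency, seed = seed,
                    n_exc = n_e, n_inh = n_i,
                    neuron_params = neuron_params, synapse_params = synapse_params)
    ),
    class = "lif_sim"
  )
}

#' @export
print.lif_sim <- function(x, ...) {
  cat(sprintf(
    "<lif_sim> %d neurons, %g ms at dt = %g ms, %d spikes\n",
    x$config$n_exc + x$config$n_inh, x$config$duration, x$config$dt, nrow(x$spikes)
  ))
  invisible(x)
}

#' Population signals from a LIF simulation
#'
#' Per-time-step population summaries: spike counts (`fr`), mean membrane
#' potential (`vm`), summed AMPA postsynaptic currents (`ampa`, positive) and
#' summed GABA postsynaptic currents (`gaba`, negative). These are the raw
#' material for the LFP proxies.
#'
#' @param sim A `lif_sim`.
#' @param population `"exc"`, `"inh"` or `"all"`.
#' @param warmup Initial transient (ms) discarded from the output.
#' @param dt_out Optional coarser output resolution (ms, a multiple of the
#'   simulation step): spike counts are summed and the other signals averaged
#'   within each output bin.
#' @return A tibble with columns `time`, `population`, `fr`, `vm`, `ampa`,
#'   `gaba`.
#' @export
population_signals <- function(sim, population = c("exc", "inh", "all"),
                               warmup = 100, dt_out = NULL) {
  stopifnot(inherits(sim, "lif_sim"))
  population <- match.arg(population)
  n_e <- sim$config$n_exc; n_i <- sim$config$n_inh
  if (population == "exc" && n_e == 0) abort("excitatory population is empty")
  if (population == "inh" && n_i == 0) abort("inhibitory population is empty")

  tr <- sim$traces
  if (population == "all") {
    w <- c(exc = n_e, inh = n_i) / (n_e + n_i)
    tr <- tr %>%
      tidyr::pivot_wider(names_from = "population",
                         values_from = c("fr", "vm", "ampa", "gaba")) %>%
      mutate(
        fr = .data$fr_exc + .data$fr_inh,
        vm = w[["exc"]] * .data$vm_exc + w[["inh"]] * .data$vm_inh,
        ampa = .data$ampa_exc + .data$ampa_inh,
        gaba = .data$gaba_exc + .data$gaba_inh,
        population = "all"
      ) %>%
      select("time", "population", "fr", "vm", "ampa", "gaba")
  } else {
    tr <- filter(tr, .data$population == .env$population)
  }
  tr <- filter(tr, .data$time > warmup + 1e-9)
  if (!is.null(dt_out)) {
    dt <- sim$config$dt
    fac <- round(dt_out / dt)
    if (abs(fac * dt - dt_out) > 1e-9) {
      abort("`dt_out` must be an integer multiple of the simulation step")
    }
    tr <- tr %>%
      mutate(bin = ceiling(round((.data$time - warmup) / dt) / fac)) %>%
      group_by(.data$bin, .data$population) %>%
      summarise(fr = sum(.data$fr), vm = mean(.data$vm),
                ampa = mean(.data$ampa), gaba = mean(.data$gaba),
                .groups = "drop") %>%
      mutate(time = warmup + .data$bin * dt_out) %>%
      select("time", "population", "fr", "vm", "ampa", "gaba") %>%
      arrange(.data$time)
  }
  tr
}
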