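# Candidate LFP proxies computed from point-network population signals.
# Every proxy is a z-scored (zero-mean, unit-variance) time series; the
# spatial amplitude factor is fitted downstream, per electrode.

# internal: z-score with the population variance convention
norm_z <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (!is.finite(s) || s == 0) abort("cannot normalise a constant (zero-variance) trace")
  (x - m) / s
}

#' Normalise a trace to zero mean and unit variance
#'
#' The `Norm[]` operation shared by all proxies: mean subtraction followed by
#' division by the (population) standard deviation.
#'
#' @param x Numeric vector, or a tibble with a `value` column.
#' @return The same shape with normalised values.
#' @export
normalize_trace <- function(x) {
  if (is.data.frame(x)) {
    x$value <- norm_z(x$value)
    x
  } else {
    norm_z(x)
  }
}

new_proxy_trace <- function(time, value, kind, params = list(), population = "exc") {
  structure(tibble(time = time, value = value),
            kind = kind, params = params, population = population,
            class = c("proxy_trace", "tbl_df", "tbl", "data.frame"))
}

# internal: series extraction by proxy kind; the sign conventions matter:
# AMPA is positive, GABA negative, so SUM_I = ampa + gaba cancels partially
# while ABS_SUM_I = ampa - gaba adds the magnitudes.
proxy_series <- function(traces, kind) {
  switch(kind,
    FR = traces$fr,
    VM = traces$vm,
    AMPA = traces$ampa,
    GABA = traces$gaba,
    SUM_I = traces$ampa + traces$gaba,
    ABS_SUM_I = traces$ampa - traces$gaba,
    abort(sprintf("unknown proxy kind '%s'", kind))
  )
}

# internal: time step of a trace tibble
trace_dt <- function(traces) {
  dts <- diff(traces$time)
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > 1e-6 * dt)) abort("trace time axis is not uniform")
  dt
}

# internal: delay a series by an integer number of bins, trimming edges.
# Positive delay means the proxy uses values `delay` in the past.
shift_trim <- function(x, k, n_lead, n_lag) {
  n <- length(x)
  idx <- (1 + n_lead):(n - n_lag)
  x[idx - k]
}

#' Simple LFP proxies
#'
#' One-variable proxies: firing rate (`FR`), mean membrane potential (`VM`),
#' summed AMPA current (`AMPA`), summed GABA current (`GABA`), their signed
#' sum (`SUM_I`, partial cancellation because AMPA and GABA carry opposite
#' signs) and the sum of absolute values (`ABS_SUM_I`, equivalent to
#' AMPA - GABA under the sign convention). The series is delayed by `delay`
#' (rounded to the grid), trimmed at the edges rather than padded, and
#' z-scored.
#'
#' @param traces Population signals from [population_signals()].
#' @param kind Proxy kind, see Details.
#' @param delay Delay (ms, non-negative multiples of the trace step).
#' @return A `proxy_trace` tibble (`time`, `value`) with kind and parameters
#'   stored as attributes.
#' @export
simple_proxy <- function(traces, kind = c("FR", "VM", "AMPA", "GABA", "SUM_I", "ABS_SUM_I"),
                         delay = 0) {
  kind <- match.arg(kind)
  dt <- trace_dt(traces)
  k <- as.integer(round(delay / dt))
  n <- nrow(traces)
  if (abs(k) >= n) abort("delay exceeds the trace span")
  x <- proxy_series(traces, kind)
  n_lead <- max(k, 0L); n_lag <- max(-k, 0L)
  idx <- (1 + n_lead):(n - n_lag)
  new_proxy_trace(traces$time[idx], norm_z(x[idx - k]), kind,
                  params = list(delay = delay))
}

#' Weighted-sum LFP proxy
#'
#' The two-current proxy `Norm[AMPA(t - tau_ampa) - alpha * GABA(t - tau_gaba)]`
#' with independent delays for the AMPA and GABA currents and a relative
#' weight `alpha`. With equal delays it reduces to the sum of absolute
#' values of currents when `alpha = 1` and to the signed current sum when
#' `alpha = -1`.
#'
#' @param traces Population signals from [population_signals()].
#' @param alpha Relative weight of the GABA contribution.
#' @param tau_ampa,tau_gaba Delays (ms), rounded to the trace step; edges are
#'   trimmed to the window on which both shifted series are defined.
#' @return A `proxy_trace`.
#' @export
ws_proxy <- function(traces, alpha, tau_ampa, tau_gaba) {
  dt <- trace_dt(traces)
  ka <- as.integer(round(tau_ampa / dt))
  kg <- as.integer(round(tau_gaba / dt))
  n <- nrow(traces)
  if (max(abs(ka), abs(kg)) >= n) abort("delay exceeds the trace span")
  n_lead <- max(ka, kg, 0L)
  n_lag <- max(-ka, -kg, 0L)
  idx <- (1 + n_lead):(n - n_lag)
  val <- traces$ampa[idx - ka] - alpha * traces$gaba[idx - kg]
  new_proxy_trace(traces$time[idx], norm_z(val), "WS",
                  params = list(alpha = alpha, tau_ampa = tau_ampa,
                                tau_gaba = tau_gaba))
}

#' Reference weighted-sum proxy (RWS)
#'
#' The fixed-parameter weighted sum
#' `Norm[AMPA(t - 6 ms) - 1.65 * GABA(t)]`, the proxy recommended for
#' synthesising LFPs from point-network models without per-site fitting.
#'
#' @param traces Population signals from [population_signals()].
#' @return A `proxy_trace` with kind `"RWS"`.
#' @export
rws_proxy <- function(traces) {
  out <- ws_proxy(traces, alpha = 1.65, tau_ampa = 6, tau_gaba = 0)
  attr(out, "kind") <- "RWS"
  out
}

#' Compute a set of proxies at once
#'
#' @param traces Population signals from [population_signals()].
#' @param kinds Character vector of proxy kinds (simple kinds plus `"RWS"`).
#' @param delay Common delay for the simple kinds (ms).
#' @return A named list of `proxy_trace` objects.
#' @export
compute_proxies <- function(traces,
                            kinds = c("FR", "VM", "AMPA", "GABA", "SUM_I", "ABS_SUM_I", "RWS"),
                            delay = 0) {
  out <- lapply(kinds, function(k) {
    if (k == "RWS") rws_proxy(traces) else simple_proxy(traces, k, delay)
  })
  names(out) <- kinds
  out
}
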