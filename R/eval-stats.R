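# Scoring proxies against the ground-truth LFP: cross-correlation delay
# search, least-squares scaling, fraction of variance explained, exhaustive
# weighted-sum parameter fitting, BIC model comparison, depth profiles and
# spectral summaries.

#' Optimal delay between an LFP trace and a proxy
#'
#' Finds the lag (on the common time grid) at which the absolute value of
#' the cross-correlation between the LFP and the lag-shifted proxy is
#' largest. A positive lag means the LFP is best predicted by proxy values
#' that far in the past. The sign of the correlation at the peak is
#' retained (it is negative on one side of the inversion point).
#'
#' @param lfp_trace,proxy_trace Numeric vectors on the same time grid.
#' @param max_lag Maximal |lag| searched (ms).
#' @param dt Time step of both traces (ms).
#' @return A list with `lag` (ms), `correlation` (signed, at the peak) and
#'   the searched `lags`/`correlations`.
#' @export
optimal_delay <- function(lfp_trace, proxy_trace, max_lag = 20, dt = 0.1) {
  n <- length(lfp_trace)
  if (length(proxy_trace) != n) abort("traces must share a time grid")
  kmax <- as.integer(round(max_lag / dt))
  if (kmax >= n / 2) abort("`max_lag` too large for the trace length")
  if (sd(lfp_trace) == 0 || sd(proxy_trace) == 0) {
    abort("flat input: cross-correlation undefined")
  }
  lags <- (-kmax):kmax
  cc <- vapply(lags, function(k) {
    if (k >= 0) {
      cor(lfp_trace[(1 + k):n], proxy_trace[1:(n - k)])
    } else {
      cor(lfp_trace[1:(n + k)], proxy_trace[(1 - k):n])
    }
  }, numeric(1))
  best <- which.max(abs(cc))
  list(lag = lags[best] * dt, correlation = cc[best],
       lags = lags * dt, correlations = cc)
}

#' Fraction of variance explained by a proxy at a given lag
#'
#' Squared Pearson correlation between the LFP and the lag-shifted,
#' least-squares-scaled proxy (identical to the R^2 of the univariate
#' regression `lfp ~ proxy`).
#'
#' @param lfp_trace,proxy_trace Numeric vectors on the same grid.
#' @param lag Lag (ms) applied to the proxy (positive: proxy from the past).
#' @param dt Time step (ms).
#' @return A list with `r_squared`, `scale`, `offset`, `rss` and `n`.
#' @export
variance_explained <- function(lfp_trace, proxy_trace, lag = 0, dt = 0.1) {
  n <- length(lfp_trace)
  k <- as.integer(round(lag / dt))
  if (abs(k) >= n) abort("lag exceeds trace length")
  if (k >= 0) {
    y <- lfp_trace[(1 + k):n]; x <- proxy_trace[1:(n - k)]
  } else {
    y <- lfp_trace[1:(n + k)]; x <- proxy_trace[(1 - k):n]
  }
  if (sd(y) == 0 || sd(x) == 0) abort("zero-variance input")
  r <- cor(y, x)
  beta <- r * sd(y) / sd(x)
  alpha0 <- mean(y) - beta * mean(x)
  res <- y - (alpha0 + beta * x)
  list(r_squared = r^2, scale = beta, offset = alpha0,
       rss = sum(res^2), n = length(y))
}

#' Fit the weighted-sum proxy by exhaustive delay search
#'
#' For every pair of delays on the two grids the LFP is regressed on the
#' shifted AMPA and GABA series (ordinary least squares, intercept
#' included); the relative weight is `alpha = -b_GABA / b_AMPA`. The delay
#' pair maximising R^2 is returned. All grid points use the same trimmed
#' analysis window so fits are comparable.
#'
#' @param lfp_trace Ground-truth LFP (numeric vector).
#' @param ampa,gaba Summed synaptic current series on the same grid.
#' @param delay_grid_a,delay_grid_g Candidate delays (ms) for the AMPA and
#'   GABA series.
#' @param dt Time step (ms).
#' @return An object of class `ws_fit`: list with `alpha`, `tau_ampa`,
#'   `tau_gaba`, `r_squared`, `rss`, `n`, `k` (free parameters), the
#'   regression coefficients and the full `grid` tibble.
#' @export
fit_ws <- function(lfp_trace, ampa, gaba,
                   delay_grid_a = seq(0, 10, by = 0.5),
                   delay_grid_g = seq(-2, 2, by = 0.5),
                   dt = 0.1) {
  n <- length(lfp_trace)
  stopifnot(length(ampa) == n, length(gaba) == n)
  ka <- as.integer(round(delay_grid_a / dt))
  kg <- as.integer(round(delay_grid_g / dt))
  n_lead <- max(ka, kg, 0L)
  n_lag <- max(-ka, -kg, 0L)
  idx <- (1 + n_lead):(n - n_lag)
  y <- lfp_trace[idx]
  sy <- sd(y)
  if (sy == 0) abort("zero-variance LFP")
  flagged <- FALSE
  one <- rep(1, length(idx))
  best <- NULL
  grid <- vector("list", length(ka) * length(kg))
  gi <- 0L
  for (ia in seq_along(ka)) {
    xa <- ampa[idx - ka[ia]]
    for (ig in seq_along(kg)) {
      xg <- gaba[idx - kg[ig]]
      xmat <- cbind(one, xa, xg)
      fit <- stats::lm.fit(xmat, y)
      co <- fit$coefficients
      deg <- anyNA(co) || fit$rank < 3L
      if (deg) {
        flagged <- TRUE
        co[is.na(co)] <- 0
      }
      rss <- sum(fit$residuals^2)
      r2 <- 1 - rss / (sy^2 * (length(y) - 1))
      gi <- gi + 1L
      grid[[gi]] <- c(tau_ampa = delay_grid_a[ia], tau_gaba = delay_grid_g[ig],
                      r_squared = r2)
      if (is.null(best) || r2 > best$r_squared) {
        best <- list(r_squared = r2, rss = rss,
                     tau_ampa = delay_grid_a[ia], tau_gaba = delay_grid_g[ig],
                     b_ampa = unname(co[2]), b_gaba = unname(co[3]),
                     offset = unname(co[1]), degenerate = deg)
      }
    }
  }
  if (flagged) {
    warn("collinear or degenerate regressors in the weighted-sum fit; alpha may be unidentifiable")
  }
  alpha <- if (best$degenerate || abs(best$b_ampa) < .Machine$double.eps) {
    NA_real_
  } else {
    -best$b_gaba / best$b_ampa
  }
  structure(
    list(alpha = alpha, tau_ampa = best$tau_ampa, tau_gaba = best$tau_gaba,
         r_squared = best$r_squared, rss = best$rss, n = length(y), k = 4L,
         b_ampa = best$b_ampa, b_gaba = best$b_gaba, offset = best$offset,
         grid = as_tibble(do.call(rbind, grid))),
    class = "ws_fit"
  )
}

#' @export
print.ws_fit <- function(x, ...) {
  cat(sprintf("<ws_fit> alpha = %.3f, tau_AMPA = %g ms, tau_GABA = %g ms, R^2 = %.3f\n",
              x$alpha, x$tau_ampa, x$tau_gaba, x$r_squared))
  invisible(x)
}

#' Bayesian information criterion under the Gaussian-noise approximation
#'
#' `BIC = n log(RSS / n) + K log(n)` with natural logarithms; lower is
#' better. At fixed residual sum of squares the criterion penalises each
#' extra free parameter by `log(n)`.
#'
#' @param rss Residual sum of squares (> 0).
#' @param n Number of samples.
#' @param k Number of free parameters.
#' @return The BIC value.
#' @export
#' @examples
#' bic(1, 100, 2)  # 100 log(0.01) + 2 log(100), about -451.3
bic <- function(rss, n, k) {
  if (!is.finite(rss) || rss <= 0) abort("`rss` must be positive")
  if (n <= 0) abort("`n` must be positive")
  n * log(rss / n) + k * log(n)
}

#' Signed amplitude profile of the LFP across depth
#'
#' Per electrode, the amplitude is the standard deviation of the signal over
#' time, signed like the baseline (time-averaged) LFP: negative above the
#' inversion point, positive below it. The inversion depth is estimated as
#' the zero crossing of the baseline closest to z = 0.
#'
#' @param lfp_array An `lfp_array`.
#' @return A `depth_profile` tibble with columns `electrode`, `depth`,
#'   `amplitude` (signed, uV) and `baseline`; the interpolated
#'   `inversion_depth` (um) is carried as an attribute.
#' @export
depth_profile <- function(lfp_array) {
  stopifnot(inherits(lfp_array, "lfp_array"))
  if (nrow(lfp_array$lfp) < 2L) abort("need at least two depths")
  depth <- lfp_array$electrodes$z
  baseline <- rowMeans(lfp_array$lfp)
  amp <- apply(lfp_array$lfp, 1L, sd) * ifelse(baseline >= 0, 1, -1)
  ord <- order(depth)
  d <- depth[ord]; b <- baseline[ord]
  cross <- which(b[-1] * b[-length(b)] < 0)
  inv <- NA_real_
  if (length(cross)) {
    z0 <- d[cross] - b[cross] * (d[cross + 1] - d[cross]) / (b[cross + 1] - b[cross])
    inv <- z0[which.min(abs(z0))]
  }
  structure(
    tibble(electrode = lfp_array$electrodes$electrode, depth = depth,
           amplitude = amp, baseline = baseline),
    inversion_depth = inv,
    class = c("depth_profile", "tbl_df", "tbl", "data.frame")
  )
}

#' Welch power spectral density with a gamma-band summary
#'
#' Averaged modified periodogram (Hann taper, 50% overlapping segments),
#' with the peak frequency and power in the gamma band (30-100 Hz by
#' default).
#'
#' @param trace Numeric vector, or a tibble with a `value` column.
#' @param fs Sampling frequency (Hz).
#' @param segment Segment length (s).
#' @param overlap Fractional overlap between segments.
#' @param band Gamma band limits (Hz).
#' @return A `spectrum_summary`: list with `spectrum` (tibble `freq`,
#'   `power`), `gamma_peak_freq` (Hz) and `gamma_peak_power`.
#' @export
psd_and_gamma <- function(trace, fs, segment = 1, overlap = 0.5,
                          band = c(30, 100)) {
  x <- if (is.data.frame(trace)) trace$value else as.numeric(trace)
  nseg <- min(length(x), round(segment * fs))
  if (nseg < 8) abort("trace too short for spectral estimation")
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))  # Hann
  u <- sum(w^2)
  acc <- numeric(nseg)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(fft(seg))^2
  }
  p <- acc / (length(starts) * fs * u)
  half <- seq_len(floor(nseg / 2) + 1L)
  p <- p[half]
  # one-sided density: double everything except DC (and Nyquist when even)
  dbl <- rep(2, length(half)); dbl[1] <- 1
  if (nseg %% 2 == 0) dbl[length(half)] <- 1
  p <- p * dbl
  freq <- (half - 1L) * fs / nseg
  inband <- which(freq >= band[1] & freq <= band[2])
  pk <- inband[which.max(p[inband])]
  structure(
    list(spectrum = tibble(freq = freq, power = p),
         gamma_peak_freq = freq[pk], gamma_peak_power = p[pk],
         fs = fs, band = band),
    class = "spectrum_summary"
  )
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf("<spectrum_summary> gamma (%g-%g Hz) peak at %.1f Hz\n",
              x$band[1], x$band[2], x$gamma_peak_freq))
  invisible(x)
}

#' Score all proxies against the ground-truth LFP, per electrode
#'
#' For every electrode and every simple proxy, searches the cross-correlation
#' peak lag, fits scale and offset by least squares and reports the fraction
#' of variance explained; the weighted-sum proxy (WS) is fitted by
#' exhaustive delay search; the reference weighted sum (RWS) uses its fixed
#' parameters and no additional lag. BIC values use K = 2 free parameters
#' (scale, delay) for simple proxies and K = 4 (scale, two delays, relative
#' amplitude) for the WS family, over a common analysis window.
#'
#' @param lfp_array An `lfp_array` (warm-up already excluded or excluded via
#'   `warmup`).
#' @param traces Population signals on the same time grid as the LFP (see
#'   [population_signals()] with `dt_out` matching the forward-model step).
#' @param proxies Character vector of proxies to score.
#' @param max_lag Delay-search half-width (ms) for simple proxies.
#' @param delay_grid_a,delay_grid_g WS delay grids (ms).
#' @param warmup Samples with `time <=  warmup` (ms) are dropped from both
#'   inputs.
#' @return A `proxy_scores` tibble: one row per electrode x proxy with
#'   `r_squared`, `lag`, `scale`, `offset`, `alpha`, `tau_ampa`, `tau_gaba`,
#'   `rss`, `n`, `k` and `bic`.
#' @export
score_proxies <- function(lfp_array, traces,
                          proxies = c("FR", "VM", "AMPA", "GABA", "SUM_I",
                                      "ABS_SUM_I", "RWS", "WS"),
                          max_lag = 20,
                          delay_grid_a = seq(0, 10, by = 0.5),
                          delay_grid_g = seq(-2, 2, by = 0.5),
                          warmup = 0) {
  stopifnot(inherits(lfp_array, "lfp_array"))
  keep_t <- lfp_array$time > warmup + 1e-9
  tmap <- match(round(lfp_array$time[keep_t], 9), round(traces$time, 9))
  if (anyNA(tmap)) abort("traces do not cover the LFP time axis at its resolution")
  tr <- traces[tmap, ]
  dt <- trace_dt(tr)
  lfp <- lfp_array$lfp[, keep_t, drop = FALSE]
  simple_kinds <- intersect(proxies, c("FR", "VM", "AMPA", "GABA", "SUM_I", "ABS_SUM_I"))
  series <- lapply(simple_kinds, function(k) norm_z(proxy_series(tr, k)))
  names(series) <- simple_kinds
  rws_tr <- if ("RWS" %in% proxies) ws_proxy(tr, 1.65, 6, 0) else NULL

  rows <- list()
  for (e in seq_len(nrow(lfp))) {
    y <- lfp[e, ]
    for (k in simple_kinds) {
      od <- optimal_delay(y, series[[k]], max_lag, dt)
      ve <- variance_explained(y, series[[k]], od$lag, dt)
      rows[[length(rows) + 1L]] <- tibble(
        electrode = lfp_array$electrodes$electrode[e],
        depth = lfp_array$electrodes$z[e],
        proxy = k, r_squared = ve$r_squared, lag = od$lag,
        scale = ve$scale, offset = ve$offset,
        alpha = NA_real_, tau_ampa = NA_real_, tau_gaba = NA_real_,
        rss = ve$rss, n = ve$n, k = 2L,
        bic = bic(ve$rss, ve$n, 2L)
      )
    }
    if (!is.null(rws_tr)) {
      yk <- y[match(round(rws_tr$time, 9), round(tr$time, 9))]
      ve <- variance_explained(yk, rws_tr$value, 0, dt)
      rows[[length(rows) + 1L]] <- tibble(
        electrode = lfp_array$electrodes$electrode[e],
        depth = lfp_array$electrodes$z[e],
        proxy = "RWS", r_squared = ve$r_squared, lag = 0,
        scale = ve$scale, offset = ve$offset,
        alpha = 1.65, tau_ampa = 6, tau_gaba = 0,
        rss = ve$rss, n = ve$n, k = 4L,
        bic = bic(ve$rss, ve$n, 4L)
      )
    }
    if ("WS" %in% proxies) {
      fit <- fit_ws(y, tr$ampa, tr$gaba, delay_grid_a, delay_grid_g, dt)
      rows[[length(rows) + 1L]] <- tibble(
        electrode = lfp_array$electrodes$electrode[e],
        depth = lfp_array$electrodes$z[e],
        proxy = "WS", r_squared = fit$r_squared, lag = NA_real_,
        scale = fit$b_ampa, offset = fit$offset,
        alpha = fit$alpha, tau_ampa = fit$tau_ampa, tau_gaba = fit$tau_gaba,
        rss = fit$rss, n = fit$n, k = 4L,
        bic = bic(fit$rss, fit$n, 4L)
      )
    }
  }
  structure(bind_rows(rows),
            class = c("proxy_scores", "tbl_df", "tbl", "data.frame"))
}
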