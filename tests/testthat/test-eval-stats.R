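# Scoring machinery: delay search, variance explained, weighted-sum fitting,
# BIC, depth profiles and spectra.

test_that("the delay search recovers constructed shifts and sign inversions", {
  withr::with_seed(2, {
    x <- as.numeric(stats::filter(rnorm(5200), rep(0.2, 5), sides = 2))
    x[is.na(x)] <- 0
  })
  dt <- 0.1
  past <- x[1:4970]    # "proxy" seen 3 ms earlier than the "lfp" below
  now <- x[31:5000]
  # positive lag: the LFP is predicted by proxy values 3 ms in the past
  expect_equal(optimal_delay(past, now, max_lag = 10, dt = dt)$lag, 3)
  # and the mirrored construction gives the mirrored lag
  expect_equal(optimal_delay(now, past, max_lag = 10, dt = dt)$lag, -3)
  neg <- optimal_delay(x[1:4000], -x[1:4000], max_lag = 5, dt = dt)
  expect_equal(neg$lag, 0)
  expect_lt(neg$correlation, -0.99)
  expect_error(optimal_delay(rep(1, 100), rnorm(100), max_lag = 2, dt = 0.1),
               "flat")
})

test_that("variance explained is exact for affine copies and near zero for noise", {
  withr::with_seed(3, {
    x <- rnorm(10000)
    y <- 2.5 * x - 4
    ve <- variance_explained(y, x, lag = 0)
    expect_equal(ve$r_squared, 1)
    expect_equal(ve$scale, 2.5, tolerance = 1e-10)
    expect_equal(ve$offset, -4, tolerance = 1e-10)
    expect_lt(variance_explained(rnorm(10000), rnorm(10000), 0)$r_squared, 0.01)
  })
})

test_that("the weighted-sum fit recovers planted parameters on synthetic mixtures", {
  fx <- make_fixture("mixture")
  truth <- attr(fx, "truth")
  fit <- fit_ws(fx$lfp, fx$traces$ampa, fx$traces$gaba, dt = fx$dt)
  expect_equal(fit$tau_ampa, truth$tau_ampa)  # exact on the grid
  expect_equal(fit$tau_gaba, truth$tau_gaba)
  expect_lt(abs(fit$alpha - truth$alpha) / truth$alpha, 0.05)
  expect_gt(fit$r_squared, 0.99)

  # the WS family is a strict superset of the single-delay current sums
  tr <- fx$traces
  simple_best <- max(vapply(seq(0, 10, 0.5), function(lag) {
    variance_explained(fx$lfp, tr$ampa - tr$gaba, lag, fx$dt)$r_squared
  }, numeric(1)))
  expect_gte(fit$r_squared, simple_best)
})

test_that("degenerate regressors are flagged in the weighted-sum fit", {
  fx <- make_fixture("mixture")
  expect_warning(
    fit <- fit_ws(fx$lfp, fx$traces$ampa, rep(0, nrow(fx$traces)), dt = fx$dt),
    "collinear|degenerate")
  expect_true(is.na(fit$alpha))
})

test_that("BIC evaluates the Gaussian approximation and penalises parameters", {
  expect_equal(bic(1, 100, 2), 100 * log(0.01) + 2 * log(100))
  expect_equal(bic(1, 100, 2), -451.31, tolerance = 1e-4)
  expect_equal(bic(2.5, 400, 0), 400 * log(2.5 / 400))  # pure fit term
  # strictly increasing in K at fixed RSS and n
  ks <- 0:6
  vals <- vapply(ks, function(k) bic(3, 500, k), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(bic(0, 100, 2), "positive")
  expect_error(bic(-1, 100, 2), "positive")
})

test_that("depth profiles sign amplitudes by baseline and locate the inversion", {
  z <- seq(-200, 200, by = 50)
  tt <- seq_len(400)
  # dipolar pattern: baseline and fluctuations flip sign at z = 25
  spatial <- tanh((z - 25) / 60)
  lfp <- outer(spatial, 1 + 0.3 * sin(tt / 7))
  arr <- lfpproxy:::new_lfp_array(lfp, electrode_grid(z = z), tt, "all", 0.3)
  prof <- depth_profile(arr)
  expect_true(all(sign(prof$amplitude) == sign(spatial)))
  expect_equal(attr(prof, "inversion_depth"), 25, tolerance = 2)
  # a constant signal has zero amplitude at every depth
  flat <- lfpproxy:::new_lfp_array(matrix(5, 5, 100),
                                   electrode_grid(z = seq(-50, 50, 25)),
                                   seq_len(100), "all", 0.3)
  expect_true(all(depth_profile(flat)$amplitude == 0))
})

test_that("spectral summaries find pure tones and preserve total power", {
  fs <- 1000
  tt <- seq(1 / fs, 8, by = 1 / fs)
  tone <- sin(2 * pi * 60 * tt)
  ps <- psd_and_gamma(tone, fs)
  expect_equal(ps$gamma_peak_freq, 60, tolerance = 1)
  withr::with_seed(4, wn <- rnorm(8 * fs))
  pw <- psd_and_gamma(wn, fs)
  # Parseval: integrated density equals the variance
  df <- diff(pw$spectrum$freq[1:2])
  expect_equal(sum(pw$spectrum$power) * df, var(wn), tolerance = 0.05)
  # flat within statistical fluctuation: band averages agree within 10%
  bands <- cut(pw$spectrum$freq, c(0, 125, 250, 375, 500))
  bp <- tapply(pw$spectrum$power, bands, mean)
  expect_lt(max(bp) / min(bp), 1.25)
  # cross-check against the raw periodogram's integrated power
  sp <- stats::spec.pgram(wn, taper = 0, plot = FALSE)
  expect_equal(sum(pw$spectrum$power) * df, 2 * mean(sp$spec) * 0.5,
               tolerance = 0.1)
})

test_that("score tables carry the R^2-equals-one identity and parameter counts", {
  tr <- synthetic_traces(n = 4000)
  # ground truth built from the traces themselves: RWS must be perfect
  w <- ws_proxy(tr, 1.65, 6, 0)
  lfp <- matrix(3 * w$value + 1, nrow = 1)
  arr <- lfpproxy:::new_lfp_array(lfp, electrode_grid(z = 0), w$time, "all", 0.3)
  sc <- score_proxies(arr, tr, proxies = c("GABA", "RWS", "WS"))
  expect_equal(sc$r_squared[sc$proxy == "RWS"], 1, tolerance = 1e-10)
  expect_equal(sc$r_squared[sc$proxy == "WS"], 1, tolerance = 1e-8)
  expect_equal(sc$alpha[sc$proxy == "WS"], 1.65, tolerance = 1e-6)
  expect_equal(sc$k[sc$proxy == "GABA"], 2L)
  expect_equal(sc$k[sc$proxy == "RWS"], 4L)
  g <- glance(sc)
  expect_true(all(g$proxy[g$mean_r_squared > 0.999] %in% c("RWS", "WS")))
})
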