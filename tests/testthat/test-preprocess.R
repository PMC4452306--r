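# Preprocessing stream: zero-phase Butterworth filtering, EMD, Hilbert
# envelopes, downsampling, Chauvenet rejection, MBLL, epoching,
# normalization and channel selection.

test_that("zero-phase bandpass rejects DC and passes in-band tones", {
  fs <- 2048
  # DC-offset constant input is annihilated
  const <- nvc_ts(rep(5, 4 * fs), fs)
  out <- butterworth_filter(const, c(5, 14), 4, "bandpass")
  trim <- fs:(3 * fs)
  expect_lt(max(abs(out$values[trim])), 1e-6 * 5)

  # 9 Hz unit sine passes with interior amplitude within 2% of 1
  t <- seq(0, 6, by = 1 / fs)
  x <- nvc_ts(sin(2 * pi * 9 * t), fs)
  y <- butterworth_filter(x, c(5, 14), 4, "bandpass")
  i <- (2 * fs):(length(t) - 2 * fs)
  expect_equal(max(abs(y$values[i])), 1, tolerance = 0.02)

  # zero-phase: cross-correlation of input and output peaks at lag 0
  cc <- ccf(y$values[i], x$values[i], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0, ignore_attr = TRUE)

  expect_error(butterworth_filter(x, c(5, 2000), 4, "bandpass"), "Nyquist")
})

test_that("filtering, downsampling and smoothing are linear operators", {
  fs <- 256
  set.seed(3)
  x <- rnorm(4 * fs); y <- rnorm(4 * fs)
  al <- 2.5; be <- -1.3
  lin_check <- function(op) {
    lhs <- op(nvc_ts(al * x + be * y, fs))$values
    rhs <- al * op(nvc_ts(x, fs))$values + be * op(nvc_ts(y, fs))$values
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
  lin_check(function(ts) butterworth_filter(ts, c(5, 14), 4, "bandpass"))
  lin_check(function(ts) downsample(ts, 25))
  lin_check(function(ts) nvc_ts(moving_average(ts$values, 30), fs))
})

test_that("EMD satisfies completeness and isolates a single tone", {
  fs <- 256
  # strictly increasing ramp: no extrema, no IMFs
  ramp <- nvc_ts(seq(0, 1, length.out = 100), fs)
  dec <- emd(ramp)
  expect_identical(length(dec$imfs), 0L)
  expect_equal(dec$residual$values, ramp$values)

  # single 9 Hz tone: IMF1 carries it
  t <- seq(0, 4, by = 1 / fs)
  tone <- nvc_ts(sin(2 * pi * 9 * t), fs)
  dec <- emd(tone)
  i <- fs:(length(t) - fs)
  expect_gt(cor(dec$imfs[[1]]$values[i], tone$values[i]), 0.99)

  # completeness for a composite signal
  set.seed(4)
  x <- nvc_ts(sin(2 * pi * 9 * t) + 0.5 * sin(2 * pi * 1.1 * t) +
                0.1 * rnorm(length(t)), fs)
  dec <- emd(x)
  recon <- Reduce(`+`, lapply(dec$imfs, `[[`, "values")) +
    dec$residual$values
  expect_lt(max(abs(x$values - recon)), 1e-9 * diff(range(x$values)))
})

test_that("Hilbert envelope recovers known instantaneous amplitudes", {
  fs <- 256
  t <- seq(0, 4, by = 1 / fs)
  i <- fs:(length(t) - fs)
  A <- 2.7
  env <- hilbert_envelope(nvc_ts(A * sin(2 * pi * 9 * t), fs))
  expect_equal(mean(env$values[i]), A, tolerance = 0.02)
  expect_true(all(env$values >= 0))

  expect_true(all(hilbert_envelope(nvc_ts(numeric(100) , fs))$values == 0))

  # linear-ramp AM tone: envelope tracks the ramp
  ramp <- seq(0.2, 2, length.out = length(t))
  env <- hilbert_envelope(nvc_ts(ramp * sin(2 * pi * 9 * t), fs))
  rmse <- sqrt(mean((env$values[i] - ramp[i])^2))
  expect_lt(rmse, 0.03 * max(ramp))
})

test_that("downsampling preserves slow content on the target grid", {
  fs <- 2048
  const <- downsample(nvc_ts(rep(2.5, fs), fs), 25)
  expect_equal(const$values, rep(2.5, length(const$values)),
               tolerance = 1e-9)
  expect_equal(const$fs, 25)

  n <- 4 * fs
  out <- downsample(nvc_ts(rnorm(n), fs), 25)
  expect_lte(abs(length(out$values) - round(n * 25 / 2048)), 1)

  t <- seq(0, 8, by = 1 / fs)
  sine <- downsample(nvc_ts(sin(2 * pi * 1 * t), fs), 25)
  truth <- sin(2 * pi * 1 * ts_time(sine))
  expect_gt(cor(sine$values, truth), 0.999)

  expect_error(downsample(nvc_ts(rnorm(100), 25), 50), "exceeds")
})

test_that("Chauvenet cleaning removes constructed spikes and little else", {
  # threshold oracle: qnorm(1 - 1/(4N))
  expect_equal(chauvenet_threshold(100), qnorm(1 - 1 / 400),
               tolerance = 1e-12)
  expect_equal(chauvenet_threshold(100), 2.8070338, tolerance = 1e-6)

  const <- chauvenet_clean(nvc_ts(rep(1, 200), 25))
  expect_true(all(const$kept))

  # smooth sine plus one 20-sigma spike: exactly that index removed
  t <- seq(0, 40, by = 1 / 25)
  v <- sin(2 * pi * 0.05 * t)
  spike_at <- 500L
  dev_sd <- sd(v - moving_average(v, 30))
  v[spike_at] <- v[spike_at] + 20 * dev_sd * 10
  cl <- chauvenet_clean(nvc_ts(v, 25))
  expect_identical(which(!cl$kept), spike_at)

  # pure Gaussian noise: < 1% of 1e4 samples rejected
  set.seed(5)
  g <- chauvenet_clean(nvc_ts(rnorm(1e4), 25))
  expect_lt(mean(!g$kept), 0.01)
})

test_that("MBLL round-trips known concentration changes", {
  oc <- default_optical_constants()
  fs <- 25
  n <- 500
  set.seed(6)
  hbo_true <- 0.8 * sin(2 * pi * 0.02 * seq_len(n) / fs)   # uM
  hbr_true <- -0.3 * sin(2 * pi * 0.02 * seq_len(n) / fs + 1)
  L <- 3.3  # cm
  A <- L * oc$dpf * oc$extinction
  dOD <- cbind(hbo_true, hbr_true) %*% t(A)
  I0 <- c(1.0, 1.2, 0.9, 1.1)
  I <- sweep(10^(-dOD), 2, I0, "*")
  # scale so the temporal-mean baseline matches the assumed I0
  I <- sweep(I, 2, colMeans(I) / I0, "/")
  rec <- nirs_record(I, fs = fs)
  out <- mbll(rec, detrend = FALSE, lowpass_hz = NULL)
  # recovery up to the mean shift the baseline convention introduces
  expect_lt(max(abs((out$hbo$values - mean(out$hbo$values)) -
                      (hbo_true - mean(hbo_true)))), 1e-9)
  expect_lt(max(abs((out$hbr$values - mean(out$hbr$values)) -
                      (hbr_true - mean(hbr_true)))), 1e-9)

  # constant intensities give identically zero concentrations
  flat <- mbll(nirs_record(matrix(1, 300, 4), fs = fs),
               detrend = FALSE, lowpass_hz = NULL)
  expect_true(all(abs(flat$hbo$values) < 1e-12))

  # 2-wavelength square system matches the closed-form solve
  rec2 <- nirs_record(I[, c(1, 4)], fs = fs,
                      wavelengths_nm = oc$wavelengths_nm[c(1, 4)],
                      dpf = oc$dpf[c(1, 4)],
                      extinction = oc$extinction[c(1, 4), ])
  out2 <- mbll(rec2, detrend = FALSE, lowpass_hz = NULL)
  A2 <- L * oc$dpf[c(1, 4)] * oc$extinction[c(1, 4), ]
  dOD2 <- -log10(sweep(I[, c(1, 4)], 2, colMeans(I[, c(1, 4)]), "/"))
  direct <- t(solve(A2, t(dOD2)))
  expect_equal(out2$hbo$values, direct[, 1], tolerance = 1e-9)

  # singular system is reported with the wavelengths involved
  expect_error(
    mbll(nirs_record(I[, c(1, 2)], fs = fs, wavelengths_nm = c(690, 690),
                     dpf = c(6, 6),
                     extinction = oc$extinction[c(1, 1), ])),
    "690")
})

test_that("epoch extraction is exact slicing with boundary errors", {
  x <- nvc_ts(seq_len(2000), 25)
  eps <- extract_epochs(x, onsets = 10, stim_dur_s = 15, pre_s = 5,
                        post_s = 5)
  expect_identical(length(eps[[1]]$values), 625L)  # 25 s x 25 Hz
  expect_equal(eps[[1]]$t0, 5)

  two <- extract_epochs(x, onsets = c(10, 40), stim_dur_s = 15)
  i0 <- round(5 * 25) + 1
  expect_identical(two[[1]]$values, x$values[i0:(i0 + 624)])

  expect_error(extract_epochs(x, onsets = 0), "outside")
})

test_that("smoothing and normalization give unit-variance epochs", {
  set.seed(7)
  ep <- nvc_ts(rnorm(625), 25)
  out <- smooth_normalize(ep)
  expect_equal(sd(out$values), 1, tolerance = 1e-12)

  expect_error(smooth_normalize(nvc_ts(rep(2, 625), 25)), "degenerate")

  # smoothing raises the lag-1 autocorrelation of white noise
  ac <- function(v) cor(v[-1], v[-length(v)])
  expect_gt(ac(out$values), ac(ep$values))
})

test_that("channel selection applies both criteria and ranks by |r|", {
  fs <- 25
  pulse <- nvc_ts(rep(c(1, 0), each = 250), fs)
  envs <- list(
    exact = nvc_ts(-pulse$values, fs),                      # |r| = 1
    mid = nvc_ts(-0.6 * pulse$values +
                   0.8 * sd(pulse$values) *
                   sin(2 * pi * 3.1 * seq_len(500) / fs), fs),
    none = nvc_ts(sin(2 * pi * 0.9 * seq_len(500) / fs), fs))
  hbo <- list(big = nvc_ts(c(rep(0, 250), rep(0.9, 250)), fs),
              small = nvc_ts(c(rep(0, 250), rep(0.4, 250)), fs))
  sel <- select_channels(envs, hbo, pulse, r_min = 0.3, hbo_min_um = 0.5)
  expect_identical(sel$eeg$channel[1], "exact")
  expect_equal(abs(sel$eeg$r[1]), 1, tolerance = 1e-12)
  expect_false("none" %in% sel$eeg$channel)
  expect_identical(sel$nirs$channel, "big")   # 0.4 uM channel excluded

  # ranking equals brute-force |r| ordering
  brute <- sort(sapply(envs, function(e) abs(cor(e$values, pulse$values))),
                decreasing = TRUE)
  expect_identical(sel$eeg$channel, names(brute)[brute >= 0.3])

  expect_warning(select_channels(envs["none"], hbo, pulse), "no EEG")
})
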