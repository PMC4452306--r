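# Synthetic mu-rhythm EEG and NIRS oxy-hemoglobin generator with known
# ground-truth gamma kernels. Serves both as the package's validation
# experiment and as its fixture generator: every dataset is a pure
# function of (config, seed).

#' Simulation configuration
#'
#' Describes one synthetic EEG-NIRS experiment: an amplitude-modulated
#' 9 Hz mu carrier whose envelope dips during eight 20 s desynchronization
#' blocks (40 s period), and oxy-hemoglobin responses generated from the
#' forward model with known gamma kernels, degraded by white Gaussian
#' noise titrated by an amplitude ratio (AR) in dB.
#'
#' The AR convention (the one consistent with "-Inf dB = no noise" and
#' with monotone degradation): `ar_db = 20 * log10(sd_noise / sd_signal)`.
#'
#' @param carrier_hz mu carrier frequency (Hz).
#' @param n_pulses number of stimulus pulses.
#' @param pulse_width_s,pulse_period_s pulse width and period (s);
#'   width must be smaller than period.
#' @param kaiser_len,kaiser_beta Kaiser smoothing window length (samples at
#'   `nirs_fs`) and shape. 250 samples at 25 Hz give the 10 s window whose
#'   half-width produces the ~5 s envelope-dip onset lag. The shape is a
#'   package default (strong sidelobe suppression); it is not prescribed.
#' @param eeg_fs,nirs_fs sampling rates (Hz).
#' @param gamma_sets list of ground-truth kernels, each `c(tau, n, d)`.
#'   The five defaults span tau 0.3-0.6 s, n 2-4, d 2-3 s; set 1 is
#'   `(0.3, 2, 2)`.
#' @param a,b forward-model gain and offset.
#' @param ar_db_list noise amplitude ratios in dB; `-Inf` means no noise.
#' @param nirs_noise_mod_hz frequency of the sinusoid multiplying the NIRS
#'   noise (emulating cardiac-band physiological noise).
#' @param trailing_rest_s rest appended after the last pulse so every
#'   35 s analysis window fits.
#' @param seed master seed; all randomness derives from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(carrier_hz = 9, n_pulses = 8L, pulse_width_s = 20,
                       pulse_period_s = 40, kaiser_len = 250L,
                       kaiser_beta = 8, eeg_fs = 2048, nirs_fs = 25,
                       gamma_sets = default_gamma_sets(),
                       a = 1, b = 0,
                       ar_db_list = c(-Inf, 0, 4, 8, 16),
                       nirs_noise_mod_hz = 0.5,
                       trailing_rest_s = 20, seed = 1L) {
  if (pulse_width_s < 0 || pulse_width_s >= pulse_period_s)
    stop("need 0 <= pulse_width_s < pulse_period_s")
  if (pulse_width_s == 0) stop("pulse_width_s of zero is degenerate")
  if (n_pulses < 1) stop("n_pulses must be >= 1")
  if (kaiser_len < 1) stop("kaiser_len must be >= 1")
  if (eeg_fs <= 0 || nirs_fs <= 0) stop("sampling rates must be > 0")
  if (carrier_hz >= eeg_fs / 2) stop("carrier above EEG Nyquist")
  for (gs in gamma_sets) {
    if (gs[1] <= 0 || gs[2] < 1 || gs[2] != round(gs[2]) || gs[3] < 0)
      stop("gamma_sets entries must satisfy tau > 0, integer n >= 1, d >= 0")
  }
  structure(list(carrier_hz = carrier_hz, n_pulses = as.integer(n_pulses),
                 pulse_width_s = pulse_width_s,
                 pulse_period_s = pulse_period_s,
                 kaiser_len = as.integer(kaiser_len),
                 kaiser_beta = kaiser_beta, eeg_fs = eeg_fs,
                 nirs_fs = nirs_fs, gamma_sets = gamma_sets, a = a, b = b,
                 ar_db_list = ar_db_list,
                 nirs_noise_mod_hz = nirs_noise_mod_hz,
                 trailing_rest_s = trailing_rest_s,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default ground-truth gamma kernels
#'
#' Five `(tau, n, d)` kernels spanning peak-time constants of 0.3-0.6 s,
#' shapes 2-4 and delays 2-3 s, i.e. physiologically plausible
#' oxy-hemoglobin responses to median nerve stimulation.
#' @return list of length-3 numeric vectors.
#' @export
default_gamma_sets <- function() {
  list(c(0.30, 2, 2.0),
       c(0.58, 4, 2.6),
       c(0.30, 3, 3.0),
       c(0.45, 2, 2.2),
       c(0.50, 3, 2.8))
}

#' Rectangular stimulus pulse train
#'
#' Binary 0/1 train at the NIRS rate, first onset at t = 0, with trailing
#' rest appended after the last pulse.
#'
#' @param cfg a `sim_config`.
#' @return binary `nvc_ts` at `cfg$nirs_fs`.
#' @export
make_stimulus_train <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  fs <- cfg$nirs_fs
  total_s <- cfg$n_pulses * cfg$pulse_period_s + cfg$trailing_rest_s
  t <- (seq_len(round(total_s * fs)) - 1) / fs
  phase <- t %% cfg$pulse_period_s
  on <- (phase < cfg$pulse_width_s - 1e-12) & (t < cfg$n_pulses * cfg$pulse_period_s)
  nvc_ts(as.numeric(on), fs, 0)
}

# Kaiser window via the zeroth-order modified Bessel function
kaiser_window <- function(n, beta) {
  if (n == 1L) return(1)
  k <- seq(0, n - 1)
  x <- beta * sqrt(pmax(1 - (2 * k / (n - 1) - 1)^2, 0))
  besselI(x, 0, expon.scaled = TRUE) * exp(x - beta) / besselI(beta, 0, expon.scaled = TRUE)
}

#' Smoothed, sign-reversed modulation wave
#'
#' Convolves the pulse train with a unit-area Kaiser window (causal
#' convolution), then reverses the sign, producing the desynchronization
#' modulation `m(t)` in [-1, 0]. The causal smoothing shifts the dip
#' onsets by about half the window length (~5 s at the defaults).
#'
#' @param pulse binary `nvc_ts` at the NIRS rate.
#' @param kaiser_len window length in samples.
#' @param kaiser_beta window shape.
#' @return modulation `nvc_ts`, same rate and length as `pulse`.
#' @export
make_modulation <- function(pulse, kaiser_len = 250L, kaiser_beta = 8) {
  stopifnot(is_nvc_ts(pulse))
  n <- length(pulse$values)
  if (kaiser_len > n) stop("kaiser_len exceeds the signal length")
  w <- kaiser_window(kaiser_len, kaiser_beta)
  w <- w / sum(w)
  sm <- if (kaiser_len == 1L) pulse$values else
    stats::convolve(pulse$values, rev(w), type = "open")[seq_len(n)]
  nvc_ts(-sm, pulse$fs, pulse$t0)
}

#' Amplitude-modulate the mu carrier
#'
#' `y(t) = (1 + m(t)) * c(t)` with `c(t) = sin(2 pi f t)`. The modulation
#' wave, built at the NIRS rate (where the 250-sample Kaiser window has its
#' stated 10 s span), is linearly interpolated onto the EEG sample grid
#' first.
#'
#' @param m modulation `nvc_ts` at the NIRS rate.
#' @param carrier_hz carrier frequency (Hz), below the EEG Nyquist.
#' @param eeg_fs EEG sampling rate (Hz).
#' @return modulated EEG `nvc_ts` at `eeg_fs`.
#' @export
am_modulate <- function(m, carrier_hz = 9, eeg_fs = 2048) {
  stopifnot(is_nvc_ts(m))
  if (carrier_hz >= eeg_fs / 2) stop("carrier at or above Nyquist")
  t_in <- ts_time(m)
  n_out <- floor((length(m$values) - 1) * eeg_fs / m$fs) + 1L
  t_out <- m$t0 + (seq_len(n_out) - 1) / eeg_fs
  m_up <- stats::approx(t_in, m$values, xout = t_out, rule = 2)$y
  y <- (1 + m_up) * sin(2 * pi * carrier_hz * t_out)
  nvc_ts(y, eeg_fs, m$t0)
}

#' Ground-truth oxy-hemoglobin from the forward model
#'
#' Thin delegation to [forward_predict()]: the clean simulated response is
#' the forward model applied to the (standard-deviation normalized) EEG
#' spectral envelope.
#'
#' @param envelope envelope `nvc_ts` at the NIRS rate, amplitude-normalized
#'   by its standard deviation.
#' @param gp `gamma_params` (or `c(tau, n, d)`).
#' @param a,b gain and offset.
#' @return clean response `nvc_ts`.
#' @export
simulate_hbo <- function(envelope, gp, a = 1, b = 0) {
  if (!inherits(gp, "gamma_params"))
    gp <- gamma_params(gp[1], gp[2], gp[3])
  forward_predict(envelope, gp, a, b)
}

#' Add white Gaussian noise at a given amplitude ratio
#'
#' Noise standard deviation is `sd(signal) * 10^(ar_db / 20)`;
#' `ar_db = -Inf` returns the input unchanged.
#'
#' @param ts input `nvc_ts`.
#' @param ar_db amplitude ratio in dB.
#' @param seed RNG seed (local to this call).
#' @return noisy `nvc_ts`.
#' @export
add_wgn <- function(ts, ar_db, seed = 1L) {
  stopifnot(is_nvc_ts(ts))
  if (identical(ar_db, -Inf)) return(ts)
  s <- stats::sd(ts$values)
  if (s == 0) stop("zero-variance input with finite amplitude ratio")
  noise <- with_local_seed(seed, stats::rnorm(length(ts$values))) *
    s * 10^(ar_db / 20)
  nvc_ts(ts$values + noise, ts$fs, ts$t0)
}

#' Add sinusoid-modulated white Gaussian noise
#'
#' Noise term `w(t) * sin(2 pi mod_hz t)` with `w` white Gaussian, scaled
#' so the noise term's standard deviation meets the amplitude-ratio
#' definition. Emulates cardiac-band physiological contamination of the
#' NIRS channel.
#'
#' @inheritParams add_wgn
#' @param mod_hz modulating frequency (Hz).
#' @return noisy `nvc_ts`.
#' @export
add_modulated_wgn <- function(ts, ar_db, mod_hz = 0.5, seed = 1L) {
  stopifnot(is_nvc_ts(ts))
  if (identical(ar_db, -Inf)) return(ts)
  s <- stats::sd(ts$values)
  if (s == 0) stop("zero-variance input with finite amplitude ratio")
  carrier <- sin(2 * pi * mod_hz * ts_time(ts))
  rms <- sqrt(mean(carrier^2))
  if (rms == 0) stop("degenerate modulating sinusoid")
  w <- with_local_seed(seed, stats::rnorm(length(ts$values)))
  noise <- w * carrier * (s * 10^(ar_db / 20) / rms)
  nvc_ts(ts$values + noise, ts$fs, ts$t0)
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a full EEG-NIRS dataset
#'
#' Composes the generator: stimulus train, Kaiser-smoothed sign-reversed
#' modulation, amplitude modulation of the mu carrier, EMD/Hilbert
#' extraction of the IMF1 spectral envelope (downsampled to the NIRS
#' rate), and forward-model oxy-hemoglobin for every ground-truth kernel
#' and amplitude ratio. Epoch windows span each pulse start to 15 s past
#' its end.
#'
#' @param cfg a `sim_config`.
#' @return object of class `sim_dataset` with elements `eeg`,
#'   `true_envelope` (noise-free `1 + m(t)` at the NIRS rate), `envelope`
#'   (IMF1 spectral envelope, std-normalized, NIRS rate), `hbo_clean` and
#'   `hbo_noisy` (per gamma set / per amplitude ratio, std-normalized),
#'   `epoch_windows` (data frame of start/end times), and `ground_truth`
#'   (the config).
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  pulse <- make_stimulus_train(cfg)
  m <- make_modulation(pulse, cfg$kaiser_len, cfg$kaiser_beta)
  eeg <- am_modulate(m, cfg$carrier_hz, cfg$eeg_fs)
  # simulated EEG is already narrow-band: envelope chain without bandpass
  env <- spectral_envelope(eeg, band = NULL, target_fs = cfg$nirs_fs)
  env_n <- nvc_ts(env$values / stats::sd(env$values), env$fs, env$t0)

  onsets <- (seq_len(cfg$n_pulses) - 1) * cfg$pulse_period_s
  windows <- data.frame(epoch = seq_len(cfg$n_pulses), start = onsets,
                        end = onsets + cfg$pulse_width_s + 15)

  hbo_clean <- vector("list", length(cfg$gamma_sets))
  hbo_noisy <- vector("list", length(cfg$gamma_sets))
  for (k in seq_along(cfg$gamma_sets)) {
    f <- simulate_hbo(env_n, cfg$gamma_sets[[k]], cfg$a, cfg$b)
    f_n <- nvc_ts(f$values / stats::sd(f$values), f$fs, f$t0)
    hbo_clean[[k]] <- f_n
    hbo_noisy[[k]] <- list()
    for (j in seq_along(cfg$ar_db_list)) {
      ar <- cfg$ar_db_list[j]
      hbo_noisy[[k]][[j]] <- add_modulated_wgn(
        f_n, ar, cfg$nirs_noise_mod_hz,
        seed = child_seed(cfg$seed, k * 100 + j))
    }
    names(hbo_noisy[[k]]) <- as.character(cfg$ar_db_list)
  }

  structure(list(eeg = eeg,
                 true_envelope = nvc_ts(1 + m$values, m$fs, m$t0),
                 envelope = env_n,
                 pulse = pulse,
                 hbo_clean = hbo_clean, hbo_noisy = hbo_noisy,
                 epoch_windows = windows, ground_truth = cfg),
            class = "sim_dataset")
}

#' Epoch pairs from a simulated dataset
#'
#' Extracts the per-pulse analysis windows (pulse start to 15 s past its
#' end) and assembles input/output epoch pairs the way the recovery study
#' fits them: the epoch envelope and the epoch response are each normalized
#' by their own standard deviation, the clean epoch response is generated
#' by the forward model from the epoch envelope, and noise at the requested
#' amplitude ratio is then titrated into both sides (plain white noise into
#' the envelope, sinusoid-modulated white noise into the response).
#'
#' @param ds a `sim_dataset`.
#' @param set_idx which ground-truth kernel (1-based index).
#' @param ar_db amplitude ratio for both channels; `-Inf` for clean pairs.
#' @param seed seed for the noise draws (default derives from the config).
#' @return list of `epoch_pair`, one per pulse.
#' @export
simulated_epochs <- function(ds, set_idx = 1L, ar_db = -Inf, seed = NULL) {
  stopifnot(inherits(ds, "sim_dataset"))
  cfg <- ds$ground_truth
  if (set_idx < 1 || set_idx > length(cfg$gamma_sets))
    stop("set_idx out of range")
  if (is.null(seed)) seed <- child_seed(cfg$seed, set_idx)
  gp <- cfg$gamma_sets[[set_idx]]
  out <- vector("list", nrow(ds$epoch_windows))
  for (i in seq_len(nrow(ds$epoch_windows))) {
    w <- ds$epoch_windows[i, ]
    g <- ts_window(ds$envelope, w$start, w$end)
    g_n <- nvc_ts(g$values / stats::sd(g$values), g$fs, g$t0)
    f <- simulate_hbo(g_n, gp, cfg$a, cfg$b)
    f_n <- nvc_ts(f$values / stats::sd(f$values), f$fs, f$t0)
    g_fit <- add_wgn(g_n, ar_db, seed = child_seed(seed, 2L * i))
    f_fit <- add_modulated_wgn(f_n, ar_db, cfg$nirs_noise_mod_hz,
                               seed = child_seed(seed, 2L * i + 1L))
    out[[i]] <- epoch_pair(g_fit, f_fit, stim_onset_s = w$start,
                           stim_dur_s = cfg$pulse_width_s,
                           eeg_channel = "sim", nirs_channel = "sim",
                           id = sprintf("set%d_ar%s_ep%d", set_idx,
                                        format(ar_db), i))
  }
  out
}
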