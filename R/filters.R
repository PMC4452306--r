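# Butterworth IIR design (bilinear transform) and zero-phase filtering.
# Implemented here because the method depends on specific filter orders and
# zero-phase behaviour and no IIR design routine ships with base R.

# analog Butterworth lowpass prototype poles (unit cutoff, rad/s)
butter_prototype <- function(order) {
  k <- seq_len(order)
  exp(1i * pi * (2 * k + order - 1) / (2 * order))
}

# polynomial coefficients (descending powers) from roots, forced real
poly_from_roots <- function(r) {
  p <- 1
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  Re(p)
}

#' Design a digital Butterworth filter
#'
#' Bilinear-transform design of a lowpass, highpass or bandpass Butterworth
#' filter. For `bandpass` the returned filter has order `2 * order`.
#'
#' @param order analog prototype order (>= 1).
#' @param cutoff_hz scalar cutoff (low/highpass) or length-2 band edges in Hz.
#' @param fs sampling rate in Hz.
#' @param type one of "lowpass", "highpass", "bandpass".
#' @return list with numerator `b` and denominator `a` coefficients.
#' @export
butter_design <- function(order, cutoff_hz, fs,
                          type = c("lowpass", "highpass", "bandpass")) {
  type <- match.arg(type)
  if (order < 1 || order != round(order)) stop("`order` must be a positive integer")
  if (any(cutoff_hz <= 0) || any(cutoff_hz >= fs / 2))
    stop("cutoff frequencies must lie strictly inside (0, fs/2)")
  fs2 <- 2 * fs
  warp <- function(f) fs2 * tan(pi * f / fs)
  p0 <- butter_prototype(order)

  if (type == "lowpass") {
    wc <- warp(cutoff_hz[1L])
    poles <- wc * p0
    zeros <- complex(0)
    gain <- wc^order
  } else if (type == "highpass") {
    wc <- warp(cutoff_hz[1L])
    poles <- wc / p0
    zeros <- rep(0 + 0i, order)
    gain <- 1
  } else {
    if (length(cutoff_hz) != 2L || cutoff_hz[2L] <= cutoff_hz[1L])
      stop("bandpass needs increasing length-2 cutoff_hz")
    wl <- warp(cutoff_hz[1L]); wh <- warp(cutoff_hz[2L])
    bw <- wh - wl; w0 <- sqrt(wl * wh)
    b2 <- p0 * bw / 2
    poles <- c(b2 + sqrt(b2^2 - w0^2), b2 - sqrt(b2^2 - w0^2))
    zeros <- rep(0 + 0i, order)
    gain <- bw^order
  }

  # bilinear transform s -> z
  zd_p <- (fs2 + poles) / (fs2 - poles)
  zd_z <- (fs2 + zeros) / (fs2 - zeros)
  # zeros mapped from infinity land at z = -1
  zd_z <- c(zd_z, rep(-1 + 0i, length(poles) - length(zeros)))
  gain_d <- gain * Re(prod(fs2 - zeros) / prod(fs2 - poles))

  b <- gain_d * poly_from_roots(zd_z)
  a <- poly_from_roots(zd_p)
  list(b = b, a = a, sos = build_sos(zd_z, zd_p, gain_d))
}

# group digital zeros/poles into biquad sections; high-order transfer
# functions with poles clustered near the unit circle are numerically
# fragile in direct form, so filtering runs through this cascade
build_sos <- function(zeros, poles, gain) {
  pair_up <- function(r) {
    r <- r[order(-Mod(r))]
    pairs <- list()
    used <- rep(FALSE, length(r))
    for (i in seq_along(r)) {
      if (used[i]) next
      used[i] <- TRUE
      if (abs(Im(r[i])) > 1e-10) {
        j <- which(!used & abs(Re(r) - Re(r[i])) < 1e-8 &
                     abs(Im(r) + Im(r[i])) < 1e-8)[1L]
        used[j] <- TRUE
        pairs[[length(pairs) + 1L]] <- c(r[i], r[j])
      } else {
        j <- which(!used & abs(Im(r)) <= 1e-10)
        if (length(j)) {
          used[j[1L]] <- TRUE
          pairs[[length(pairs) + 1L]] <- c(r[i], r[j[1L]])
        } else {
          pairs[[length(pairs) + 1L]] <- r[i]
        }
      }
    }
    pairs
  }
  p_pairs <- pair_up(poles)
  z_pool <- zeros
  sos <- matrix(0, nrow = length(p_pairs), ncol = 6L)
  for (s in seq_along(p_pairs)) {
    pp <- p_pairs[[s]]
    zz <- complex(0)
    for (k in seq_len(min(length(pp), length(z_pool)))) {
      j <- which.min(Mod(z_pool - pp[1L]))
      zz <- c(zz, z_pool[j])
      z_pool <- z_pool[-j]
    }
    bsec <- poly_from_roots(zz)
    asec <- poly_from_roots(pp)
    sos[s, ] <- c(c(bsec, numeric(3L - length(bsec))),
                  c(asec, numeric(3L - length(asec))))
  }
  sos[1L, 1:3] <- sos[1L, 1:3] * gain
  sos
}

# single-pass filtering through a biquad cascade, zero initial conditions
sos_filter <- function(x, sos) {
  for (s in seq_len(nrow(sos))) {
    b <- sos[s, 1:3]; a <- sos[s, 4:6]
    n <- length(x)
    v <- b[1L] * x
    if (b[2L] != 0) v <- v + b[2L] * c(0, x[-n])
    if (b[3L] != 0) v <- v + b[3L] * c(0, 0, x[-c(n - 1L, n)])
    x <- if (any(a[2:3] != 0))
      as.numeric(stats::filter(v, -a[2:3], method = "recursive")) else v
  }
  x
}

#' Zero-phase (forward-backward) IIR filtering
#'
#' Applies the filter forwards and backwards so the net phase response is
#' zero. Filtering runs through the second-order-section cascade for
#' numerical robustness; edges are handled by odd-reflection padding, as
#' is conventional.
#'
#' @param x numeric vector.
#' @param filt filter design from [butter_design()].
#' @param padlen reflection pad length; default grows with the filter's
#'   impulse-response time constant so start-up transients decay inside
#'   the pad.
#' @return filtered numeric vector, same length as `x`.
#' @export
filtfilt <- function(x, filt, padlen = NULL) {
  sos <- filt$sos
  n <- length(x)
  if (is.null(padlen)) {
    # slowest pole sets the transient time constant
    r <- unlist(lapply(seq_len(nrow(sos)), function(s)
      Mod(polyroot(rev(sos[s, 4:6])))))
    r <- r[r < 1 - 1e-12]
    tc <- if (length(r)) ceiling(-7 / log(max(r))) else 0
    padlen <- max(3L * nrow(sos) * 2L, tc)
  }
  padlen <- min(padlen, n - 1L)
  if (padlen > 0) {
    pre <- 2 * x[1L] - x[seq(padlen + 1L, 2L)]
    post <- 2 * x[n] - x[seq(n - 1L, n - padlen)]
    xe <- c(pre, x, post)
  } else xe <- x
  # filter about the leading value so step transients from the zero
  # initial conditions vanish for near-constant signals
  gdc <- prod((sos[, 1] + sos[, 2] + sos[, 3]) /
                (sos[, 4] + sos[, 5] + sos[, 6]))
  c1 <- xe[1L]
  y <- sos_filter(xe - c1, sos) + c1 * gdc
  c2 <- y[length(y)]
  y <- rev(sos_filter(rev(y) - c2, sos) + c2 * gdc)
  if (padlen > 0) y[(padlen + 1L):(padlen + n)] else y
}

#' Zero-phase Butterworth filtering of a time series
#'
#' The EEG stream uses a 4th-order 5--14 Hz bandpass (to contain the mu
#' band); the NIRS stream a 3rd-order 0.5 Hz lowpass (to remove cardiac
#' oscillations). Both are applied forward-backward so no phase distortion
#' is introduced between the modalities.
#'
#' @param ts an `nvc_ts`.
#' @param band length-2 numeric `c(low, high)` for bandpass, or scalar
#'   cutoff for lowpass.
#' @param order filter order (of the analog prototype).
#' @param kind "bandpass" or "lowpass".
#' @return filtered `nvc_ts`, same sampling rate and length.
#' @export
butterworth_filter <- function(ts, band, order = 4L,
                               kind = c("bandpass", "lowpass")) {
  kind <- match.arg(kind)
  stopifnot(is_nvc_ts(ts))
  if (any(band >= ts$fs / 2))
    stop("band edge at or above the Nyquist frequency")
  des <- if (kind == "bandpass") {
    butter_design(order, band, ts$fs, "bandpass")
  } else {
    butter_design(order, band[1L], ts$fs, "lowpass")
  }
  nvc_ts(filtfilt(ts$values, des), ts$fs, ts$t0)
}

#' Hilbert (analytic-signal) amplitude envelope
#'
#' Magnitude of the analytic signal computed with the FFT one-sided
#' spectrum method. Used to turn the first intrinsic mode function into the
#' EEG spectral envelope.
#'
#' @param ts an `nvc_ts`.
#' @return non-negative `nvc_ts` of the same length.
#' @export
hilbert_envelope <- function(ts) {
  stopifnot(is_nvc_ts(ts))
  x <- ts$values
  n0 <- length(x)
  # pad to a 5-smooth length so the FFT stays O(n log n) for any input size;
  # padding only perturbs the envelope near the very edges
  n <- smooth_length(n0)
  if (n > n0) x <- c(x, numeric(n - n0))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1L] <- 1; h[n / 2 + 1L] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  analytic <- stats::fft(X * h, inverse = TRUE) / n
  nvc_ts(Mod(analytic)[seq_len(n0)], ts$fs, ts$t0)
}

# smallest length >= n whose prime factors are all in {2, 3, 5}
smooth_length <- function(n) {
  m <- n
  repeat {
    k <- m
    for (p in c(2, 3, 5)) while (k %% p == 0) k <- k / p
    if (k == 1) return(m)
    m <- m + 1
  }
}

#' Downsample with anti-alias filtering
#'
#' Zero-phase Butterworth lowpass at 0.45 of the target Nyquist-equivalent
#' rate, then interpolation onto the target sample grid. Used to bring the
#' 2048 Hz EEG spectral envelope onto the 25 Hz NIRS grid.
#'
#' @param ts an `nvc_ts`.
#' @param target_fs target sampling rate (Hz), must not exceed `ts$fs`.
#' @param aa_order anti-alias filter order.
#' @return `nvc_ts` at `target_fs`, same `t0`.
#' @export
downsample <- function(ts, target_fs, aa_order = 8L) {
  stopifnot(is_nvc_ts(ts))
  if (target_fs > ts$fs) stop("target_fs exceeds the input sampling rate")
  if (abs(target_fs - ts$fs) < 1e-12) return(ts)
  cutoff <- 0.45 * target_fs
  x <- if (cutoff < ts$fs / 2) {
    des <- butter_design(aa_order, cutoff, ts$fs, "lowpass")
    filtfilt(ts$values, des)
  } else ts$values
  t_in <- ts_time(ts)
  n_out <- floor((length(ts$values) - 1) * target_fs / ts$fs) + 1L
  t_out <- ts$t0 + (seq_len(n_out) - 1) / target_fs
  y <- stats::approx(t_in, x, xout = t_out, rule = 2)$y
  nvc_ts(y, target_fs, ts$t0)
}

#' Centered moving average
#'
#' Moving average with shrinking windows at the edges (the span contracts
#' near the boundaries instead of padding). Used for NIRS deviation
#' smoothing (span 30 = 1.2 s at 25 Hz) and epoch smoothing (4 s).
#'
#' @param x numeric vector.
#' @param span window length in samples.
#' @return smoothed numeric vector, same length.
#' @export
moving_average <- function(x, span) {
  span <- max(1L, as.integer(span))
  if (span == 1L) return(x)
  n <- length(x)
  half <- span %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (span - half - 1L), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
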