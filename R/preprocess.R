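# NIRS-side preprocessing: motion-artifact rejection (Chauvenet),
# modified Beer-Lambert law oximetry, epoch extraction and normalization,
# and correlation-based channel selection.

#' Chauvenet rejection threshold
#'
#' The criterion rejects samples whose deviation probability under a
#' normal model is below `1/(2N)`; the two-sided threshold on the
#' deviation ratio is the normal quantile `qnorm(1 - 1/(4N))`.
#'
#' @param n number of samples.
#' @return threshold in standard-deviation units.
#' @export
chauvenet_threshold <- function(n) stats::qnorm(1 - 1 / (4 * n))

#' Motion-artifact rejection by Chauvenet's criterion
#'
#' Deviations are the raw signal minus its moving-average smooth (span 30
#' points = 1.2 s at 25 Hz); the deviation ratio is the deviation divided
#' by the standard deviation of all deviations. Samples whose absolute
#' deviation ratio exceeds the Chauvenet threshold are removed and the
#' surviving segments spliced together (timestamps re-indexed
#' contiguously).
#'
#' @param ts an `nvc_ts`.
#' @param span_points moving-average span in samples.
#' @return list with `cleaned` (`nvc_ts`) and `kept` (logical mask on the
#'   input samples).
#' @export
chauvenet_clean <- function(ts, span_points = 30L) {
  stopifnot(is_nvc_ts(ts))
  n <- length(ts$values)
  if (n <= span_points) stop("signal not longer than the smoothing span")
  dev <- ts$values - moving_average(ts$values, span_points)
  s <- stats::sd(dev)
  kept <- if (s == 0) rep(TRUE, n) else
    abs(dev / s) <= chauvenet_threshold(n)
  list(cleaned = nvc_ts(ts$values[kept], ts$fs, ts$t0), kept = kept)
}

#' Default optical constants for the four-wavelength NIRS system
#'
#' Molar extinction coefficients (cm^-1 / M, compiled tabulated values for
#' oxy- and deoxy-hemoglobin) and differential pathlength factors at
#' 690 / 785 / 808 / 830 nm. These constants are a documented package
#' default, overridable in [nirs_record()]; concentration outputs depend
#' on the table used.
#'
#' @return list with `wavelengths_nm`, `extinction` (4 x 2 matrix, columns
#'   HbO / HbR, units cm^-1 uM^-1) and `dpf`.
#' @export
default_optical_constants <- function() {
  wl <- c(690, 785, 808, 830)
  # molar extinction, cm^-1/M; scaled to cm^-1/uM below
  ext_molar <- rbind(c(276,  2051.96),
                     c(735.4, 1008.0),
                     c(879.5,  744.0),
                     c(1074,   693.04))
  dimnames(ext_molar) <- list(as.character(wl), c("HbO", "HbR"))
  list(wavelengths_nm = wl, extinction = ext_molar * 1e-6,
       dpf = c(6.51, 6.26, 6.10, 5.86))
}

#' Raw NIRS intensity record for one measurement channel
#'
#' @param intensities numeric matrix, time x wavelength, strictly positive
#'   light intensities.
#' @param fs sampling rate (Hz).
#' @param wavelengths_nm wavelengths of the columns.
#' @param source_detector_mm source-detector separation (mm).
#' @param dpf per-wavelength differential pathlength factors.
#' @param extinction per-wavelength extinction matrix (cm^-1 uM^-1,
#'   columns HbO, HbR).
#' @param t0 start time (s).
#' @return object of class `nirs_record`.
#' @export
nirs_record <- function(intensities, fs = 25,
                        wavelengths_nm = NULL, source_detector_mm = 33,
                        dpf = NULL, extinction = NULL, t0 = 0) {
  intensities <- as.matrix(intensities)
  defaults <- default_optical_constants()
  if (is.null(wavelengths_nm)) wavelengths_nm <- defaults$wavelengths_nm
  if (is.null(dpf)) dpf <- defaults$dpf[seq_along(wavelengths_nm)]
  if (is.null(extinction))
    extinction <- defaults$extinction[seq_along(wavelengths_nm), , drop = FALSE]
  if (ncol(intensities) != length(wavelengths_nm))
    stop("one intensity column per wavelength required")
  if (any(intensities <= 0)) stop("light intensities must be positive")
  if (length(dpf) != length(wavelengths_nm))
    stop("one DPF per wavelength required")
  structure(list(intensities = intensities, fs = fs,
                 wavelengths_nm = wavelengths_nm,
                 source_detector_mm = source_detector_mm,
                 dpf = dpf, extinction = as.matrix(extinction), t0 = t0),
            class = "nirs_record")
}

#' Modified Beer-Lambert law: intensities to hemoglobin concentrations
#'
#' Optical-density changes `dOD = -log10(I / mean(I))` per wavelength are
#' solved, per time point, in the least-squares sense for the chromophore
#' concentration changes via
#' `dOD_l = L * DPF_l * (eps_HbO,l dHbO + eps_HbR,l dHbR)`.
#' Outputs are optionally detrended (linear) and zero-phase lowpass
#' filtered at 0.5 Hz (3rd-order Butterworth) to remove cardiac
#' oscillations.
#'
#' @param rec a `nirs_record`.
#' @param baseline optional index range used for the mean-intensity
#'   baseline; default uses the whole recording.
#' @param detrend remove a linear trend (default TRUE).
#' @param lowpass_hz cutoff for the cardiac filter, or `NULL` to skip.
#' @param lowpass_order Butterworth order for the cardiac filter.
#' @return list with `hbo` and `hbr` (`nvc_ts`, micromolar).
#' @export
mbll <- function(rec, baseline = NULL, detrend = TRUE, lowpass_hz = 0.5,
                 lowpass_order = 3L) {
  stopifnot(inherits(rec, "nirs_record"))
  I <- rec$intensities
  idx <- if (is.null(baseline)) seq_len(nrow(I)) else baseline
  I0 <- colMeans(I[idx, , drop = FALSE])
  dOD <- -log10(sweep(I, 2, I0, "/"))
  L_cm <- rec$source_detector_mm / 10
  A <- L_cm * rec$dpf * rec$extinction  # wavelengths x 2
  gram <- crossprod(A)
  if (abs(det(gram)) < 1e-18)
    stop(sprintf("singular extinction system for wavelengths {%s}",
                 paste(rec$wavelengths_nm, collapse = ", ")))
  conc <- dOD %*% A %*% solve(gram)  # time x 2, micromolar
  post <- function(x) {
    if (detrend) {
      t <- seq_along(x)
      x <- stats::residuals(stats::lm.fit(cbind(1, t), x)) + mean(x)
      x <- x - mean(x)
    }
    ts <- nvc_ts(x, rec$fs, rec$t0)
    if (!is.null(lowpass_hz))
      ts <- butterworth_filter(ts, lowpass_hz, lowpass_order, "lowpass")
    ts
  }
  list(hbo = post(conc[, 1L]), hbr = post(conc[, 2L]))
}

#' Extract stimulus-locked epochs
#'
#' One slice per onset covering `pre_s` before the onset through
#' `stim_dur_s + post_s` after it.
#'
#' @param ts an `nvc_ts`.
#' @param onsets stimulus onset times (s, absolute).
#' @param stim_dur_s stimulus duration (s).
#' @param pre_s,post_s padding before onset / after stimulus end (s).
#' @return list of `nvc_ts`, each of `(pre_s + stim_dur_s + post_s) * fs`
#'   samples.
#' @export
extract_epochs <- function(ts, onsets, stim_dur_s = 15, pre_s = 5,
                           post_s = 5) {
  stopifnot(is_nvc_ts(ts))
  fs <- ts$fs
  n <- length(ts$values)
  len <- round((pre_s + stim_dur_s + post_s) * fs)
  lapply(onsets, function(on) {
    i0 <- round((on - pre_s - ts$t0) * fs) + 1L
    if (i0 < 1L || i0 + len - 1L > n)
      stop(sprintf("epoch at onset %g s falls outside the recording", on))
    nvc_ts(ts$values[i0:(i0 + len - 1L)], fs, t0 = ts$t0 + (i0 - 1L) / fs)
  })
}

#' Smooth and amplitude-normalize one epoch
#'
#' Centered moving-average smoothing (4 s window by default) followed by
#' division by the smoothed signal's sample standard deviation, giving the
#' unit-variance traces the fit operates on.
#'
#' @param epoch an `nvc_ts`.
#' @param window_s smoothing window in seconds.
#' @return normalized `nvc_ts` with sample standard deviation 1.
#' @export
smooth_normalize <- function(epoch, window_s = 4) {
  stopifnot(is_nvc_ts(epoch))
  span <- round(window_s * epoch$fs)
  if (span >= length(epoch$values)) stop("epoch shorter than the window")
  sm <- moving_average(epoch$values, span)
  s <- stats::sd(sm)
  if (s < 1e-300) stop("degenerate epoch: zero variance after smoothing")
  nvc_ts(sm / s, epoch$fs, epoch$t0)
}

#' Select EEG and NIRS channels for modeling
#'
#' EEG channels are ranked by the absolute Pearson correlation between
#' their spectral envelope and the stimulus pulse sequence and kept when
#' `|r| >= r_min`; NIRS channels are kept when their peak-to-baseline
#' oxy-hemoglobin excursion reaches `hbo_min_um` (baseline taken as the
#' channel's 10th percentile, a robust resting level).
#'
#' @param envelopes named list of envelope `nvc_ts` (one per EEG channel).
#' @param hbo_channels named list of oxy-hemoglobin `nvc_ts` (micromolar).
#' @param pulse stimulus `nvc_ts` on the same time base as the envelopes.
#' @param r_min correlation threshold for EEG channels.
#' @param hbo_min_um concentration threshold (micromolar).
#' @return list with `eeg` (data frame: channel, r, ranked by `|r|`),
#'   `nirs` (data frame: channel, peak_um) of the selected channels.
#' @export
select_channels <- function(envelopes, hbo_channels, pulse, r_min = 0.3,
                            hbo_min_um = 0.5) {
  r <- vapply(envelopes, function(e) {
    n <- min(length(e$values), length(pulse$values))
    stats::cor(e$values[seq_len(n)], pulse$values[seq_len(n)])
  }, numeric(1))
  eeg <- data.frame(channel = names(envelopes), r = r,
                    stringsAsFactors = FALSE)
  eeg <- eeg[order(-abs(eeg$r)), , drop = FALSE]
  eeg <- eeg[abs(eeg$r) >= r_min & !is.na(eeg$r), , drop = FALSE]

  # baseline = 10th percentile (resting level), peak = maximum
  peak <- vapply(hbo_channels, function(h)
    max(h$values) - stats::quantile(h$values, 0.1, names = FALSE),
    numeric(1))
  nirs <- data.frame(channel = names(hbo_channels), peak_um = peak,
                     stringsAsFactors = FALSE)
  nirs <- nirs[nirs$peak_um >= hbo_min_um, , drop = FALSE]

  if (nrow(eeg) == 0L) warning("no EEG channel passed the correlation threshold")
  if (nrow(nirs) == 0L) warning("no NIRS channel passed the concentration threshold")
  rownames(eeg) <- rownames(nirs) <- NULL
  list(eeg = eeg, nirs = nirs)
}
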