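# Empirical mode decomposition by standard sifting: cubic-spline envelopes
# through local extrema, mean-envelope subtraction until the SD stopping
# criterion is met. Boundaries are handled by mirror extension of the
# extrema nearest each end.

local_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) return(list(max = integer(0), min = integer(0)))
  d <- diff(x)
  # collapse flat runs so plateaus register one extremum
  s <- sign(d)
  nz <- which(s != 0)
  if (length(nz) < 2L) return(list(max = integer(0), min = integer(0)))
  s_f <- s
  for (i in seq(2L, length(s_f))) if (s_f[i] == 0) s_f[i] <- s_f[i - 1L]
  ds <- diff(s_f)
  list(max = which(ds < 0) + 1L, min = which(ds > 0) + 1L)
}

# spline envelope through (idx, x[idx]) with mirror extension of `next`
# extrema beyond both ends, evaluated at every sample
spline_envelope <- function(x, idx, n) {
  t_i <- as.numeric(idx)
  v_i <- x[idx]
  k <- min(2L, length(idx) - 1L)
  if (k >= 1L) {
    left_t <- 2 * t_i[1L] - t_i[seq(k + 1L, 2L)]
    left_v <- v_i[seq(k + 1L, 2L)]
    m <- length(t_i)
    right_t <- 2 * t_i[m] - t_i[seq(m - 1L, m - k)]
    right_v <- v_i[seq(m - 1L, m - k)]
    t_i <- c(left_t, t_i, right_t)
    v_i <- c(left_v, v_i, right_v)
  }
  stats::spline(t_i, v_i, xout = seq_len(n), method = "fmm")$y
}

#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions (IMFs), fastest first,
#' plus a residual, using cubic-spline sifting. The decomposition is
#' complete by construction: the IMFs and residual sum back to the input.
#'
#' Stopping uses the standard-deviation sift criterion
#' `sum((h_prev - h)^2 / (h_prev^2 + eps)) < sift_tol` with a cap on sifts
#' per IMF; extraction stops when the residual has fewer than three
#' extrema (monotone or trivially oscillation-free) or `max_imfs` is hit.
#'
#' @param ts an `nvc_ts` (length >= 8).
#' @param max_imfs maximum number of IMFs to extract.
#' @param sift_tol SD stopping tolerance (default 0.2).
#' @param max_sifts cap on sifting iterations per IMF (default 10).
#' @return list with `imfs` (list of `nvc_ts`) and `residual` (`nvc_ts`).
#' @export
emd <- function(ts, max_imfs = 10L, sift_tol = 0.2, max_sifts = 10L) {
  stopifnot(is_nvc_ts(ts))
  x <- ts$values
  n <- length(x)
  if (n < 8L) stop("signal too short for EMD")
  imfs <- list()
  resid <- x
  for (k in seq_len(max_imfs)) {
    ex <- local_extrema(resid)
    if (length(ex$max) + length(ex$min) < 3L) break
    h <- resid
    for (s in seq_len(max_sifts)) {
      ex_h <- local_extrema(h)
      if (length(ex_h$max) < 2L || length(ex_h$min) < 2L) break
      upper <- spline_envelope(h, ex_h$max, n)
      lower <- spline_envelope(h, ex_h$min, n)
      m <- (upper + lower) / 2
      h_new <- h - m
      sd_crit <- sum((h - h_new)^2 / (h^2 + 1e-12))
      h <- h_new
      if (sd_crit < sift_tol) break
    }
    imfs[[k]] <- nvc_ts(h, ts$fs, ts$t0)
    resid <- resid - h
  }
  list(imfs = imfs, residual = nvc_ts(resid, ts$fs, ts$t0))
}

#' EEG spectral envelope from a raw trace
#'
#' Convenience chain used throughout the package: optional zero-phase
#' Butterworth bandpass, EMD, Hilbert amplitude of the first IMF, then
#' downsampling onto the NIRS sample grid. The first IMF is used because
#' its spectral content tracks the mu-band carrier and its amplitude is
#' modulated by desynchronization events.
#'
#' @param ts raw EEG `nvc_ts`.
#' @param band bandpass edges in Hz, or `NULL` to skip filtering (the
#'   simulated EEG is already narrow-band).
#' @param order bandpass order.
#' @param target_fs output rate (Hz), the NIRS rate by default.
#' @return envelope `nvc_ts` at `target_fs`.
#' @export
spectral_envelope <- function(ts, band = c(5, 14), order = 4L,
                              target_fs = 25) {
  x <- if (!is.null(band)) butterworth_filter(ts, band, order, "bandpass") else ts
  dec <- emd(x, max_imfs = 1L)
  if (length(dec$imfs) == 0L) stop("no oscillatory mode found in EEG input")
  env <- hilbert_envelope(dec$imfs[[1L]])
  downsample(env, target_fs)
}
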