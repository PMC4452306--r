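#' Uniformly sampled time series
#'
#' Lightweight container for a real-valued, uniformly sampled signal. All
#' signals handled by the package (EEG, spectral envelopes, NIRS
#' concentration series, stimulus trains) are carried in this structure.
#'
#' @param values numeric vector of samples.
#' @param fs sampling rate in Hz (> 0).
#' @param t0 time of the first sample in seconds (default 0).
#' @return An object of class `nvc_ts`.
#' @export
#' @examples
#' x <- nvc_ts(sin(2 * pi * 9 * seq(0, 1, by = 1 / 256)), fs = 256)
#' ts_duration(x)
nvc_ts <- function(values, fs, t0 = 0) {
  if (!is.numeric(values) || length(values) == 0L)
    stop("`values` must be a non-empty numeric vector")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number")
  if (!all(is.finite(values)))
    stop("`values` must be finite")
  structure(list(values = as.numeric(values), fs = as.numeric(fs),
                 t0 = as.numeric(t0)),
            class = "nvc_ts")
}

is_nvc_ts <- function(x) inherits(x, "nvc_ts")

as_nvc_ts <- function(x, fs, t0 = 0) {
  if (is_nvc_ts(x)) x else nvc_ts(x, fs, t0)
}

#' @export
print.nvc_ts <- function(x, ...) {
  cat(sprintf("<nvc_ts> %d samples @ %g Hz, t0 = %g s (%.3f s)\n",
              length(x$values), x$fs, x$t0, ts_duration(x)))
  invisible(x)
}

#' @export
length.nvc_ts <- function(x) length(x$values)

#' Sample times of a time series
#' @param x an `nvc_ts`.
#' @return numeric vector of sample times in seconds.
#' @export
ts_time <- function(x) {
  stopifnot(is_nvc_ts(x))
  x$t0 + (seq_along(x$values) - 1) / x$fs
}

#' Duration of a time series in seconds
#' @param x an `nvc_ts`.
#' @export
ts_duration <- function(x) length(x$values) / x$fs

#' Extract a time window from a time series
#'
#' @param x an `nvc_ts`.
#' @param from,to window boundaries in seconds (absolute time). The slice
#'   includes samples with `from <= t < to`.
#' @return an `nvc_ts` starting at the first retained sample.
#' @export
ts_window <- function(x, from, to) {
  stopifnot(is_nvc_ts(x), to > from)
  t <- ts_time(x)
  idx <- which(t >= from - 1e-9 & t < to - 1e-9)
  if (length(idx) == 0L)
    stop(sprintf("window [%g, %g) contains no samples", from, to))
  nvc_ts(x$values[idx], x$fs, t0 = t[idx[1L]])
}

#' Derive a child seed from a master seed
#'
#' Deterministic counter-based seed derivation used for all randomness in
#' the package: one master seed, children indexed by a counter, values
#' kept inside the 32-bit integer range. Lets any subset of a simulation
#' be reproduced in isolation.
#'
#' @param seed master seed (integer).
#' @param counter child index (integer).
#' @return derived integer seed.
#' @export
child_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(counter) * 16807) %%
               2147483647)
}
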