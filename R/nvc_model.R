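# Gamma-transfer-function forward model and the two-step (grid + simplex)
# parameter estimator linking EEG spectral envelopes to NIRS oxy-hemoglobin.

#' Gamma transfer function parameters
#'
#' The kernel is the Erlang/gamma density
#' `h(t) = ((t - d)/tau)^(n-1) exp(-(t - d)/tau) / (tau * gamma(n))` for
#' `t >= d`, zero before. `tau` sets the rise time to peak, `n` the shape,
#' `d` a pure delay. `n` is an integer in the generative model; during
#' simplex refinement it is relaxed to a continuous value (gamma(n)
#' replaces the factorial), and results report both the continuous
#' estimate and its nearest integer.
#'
#' @param tau peak-time constant in seconds (> 0).
#' @param n shape (>= 1; integer in the generative model).
#' @param d pure delay in seconds (>= 0).
#' @return object of class `gamma_params`.
#' @export
gamma_params <- function(tau, n, d) {
  if (!is.finite(tau) || tau <= 0) stop("tau must be > 0")
  if (!is.finite(n) || n < 1) stop("n must be >= 1")
  if (!is.finite(d) || d < 0) stop("d must be >= 0")
  structure(list(tau = tau, n = n, d = d), class = "gamma_params")
}

#' @export
print.gamma_params <- function(x, ...) {
  cat(sprintf("<gamma_params> tau = %g s, n = %g, d = %g s\n", x$tau, x$n, x$d))
  invisible(x)
}

#' Pointwise gamma transfer function values
#'
#' Continuous-time evaluation of the kernel; `gamma_density(d, gp)` equals
#' `1/tau` when `n = 1`.
#'
#' @param t numeric vector of times in seconds.
#' @param gp `gamma_params`.
#' @return kernel values (units 1/s).
#' @export
gamma_density <- function(t, gp) {
  out <- numeric(length(t))
  pos <- t >= gp$d
  u <- (t[pos] - gp$d) / gp$tau
  out[pos] <- u^(gp$n - 1) * exp(-u) / (gp$tau * gamma(gp$n))
  out
}

#' Sampled gamma transfer function kernel
#'
#' Returns the kernel discretised on the sampling grid. Each tap carries
#' the exact kernel mass of its sample bin (difference of the gamma CDF,
#' scaled by `fs`), so the discrete integral `sum(h) / fs` equals the
#' kernel mass captured by `duration_s` -- essentially 1 for an adequate
#' duration -- at any sampling rate, including sharply peaked kernels that
#' pointwise sampling would misrepresent at 25 Hz.
#'
#' @param gp `gamma_params`.
#' @param fs sampling rate (Hz).
#' @param duration_s kernel support to sample; default `d + 10 n tau + 1/fs`
#'   captures the tail to < 1e-4 mass for all grid parameters.
#' @param warn_truncation warn when `duration_s` cuts into the kernel
#'   support (internal callers that deliberately truncate disable this).
#' @return numeric vector of kernel taps (units 1/s).
#' @export
gamma_kernel <- function(gp, fs, duration_s = NULL, warn_truncation = TRUE) {
  if (!inherits(gp, "gamma_params")) gp <- do.call(gamma_params, as.list(gp))
  if (is.null(duration_s)) duration_s <- gp$d + 10 * gp$n * gp$tau + 1 / fs
  if (warn_truncation && duration_s < gp$d + 5 * gp$n * gp$tau)
    warning("duration_s may truncate the kernel support")
  n_tap <- max(1L, ceiling(duration_s * fs))
  edges <- (seq_len(n_tap + 1L) - 1.5) / fs  # bin i covers t in [i-1.5, i-0.5]/fs
  cdf <- stats::pgamma(pmax(edges - gp$d, 0) / gp$tau, shape = gp$n)
  diff(cdf) * fs
}

#' Forward model: predicted hemodynamic response
#'
#' `f(t) = a * (g * h)(t) + b`: causal discrete convolution of the EEG
#' spectral envelope with the gamma kernel, scaled by the sample interval,
#' truncated to the envelope's length. The envelope is zero-padded on the
#' left, so the first `d + (n-1) tau` seconds are partially transient.
#'
#' @param g envelope `nvc_ts`.
#' @param gp `gamma_params`.
#' @param a gain.
#' @param b offset.
#' @return predicted `nvc_ts` aligned with `g`.
#' @export
forward_predict <- function(g, gp, a = 1, b = 0) {
  stopifnot(is_nvc_ts(g))
  h <- gamma_kernel(gp, g$fs)
  y <- causal_conv(g$values, h) / g$fs
  nvc_ts(a * y + b, g$fs, g$t0)
}

# causal linear convolution truncated to length(x), FFT-backed
causal_conv <- function(x, h) {
  n <- length(x)
  m <- length(h)
  nfft <- stats::nextn(n + m - 1L, 2)
  X <- stats::fft(c(x, numeric(nfft - n)))
  H <- stats::fft(c(h, numeric(nfft - m)))
  Re(stats::fft(X * H, inverse = TRUE))[seq_len(n)] / nfft
}

#' Least-squares gain and offset
#'
#' Ordinary least squares for `y ~ a * x + b`, used at every grid candidate
#' after convolution.
#'
#' @param x predicted-shape sequence.
#' @param y observed sequence.
#' @return list with `a`, `b`.
#' @export
solve_gain_offset <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3")
  sxx <- sum((x - mean(x))^2)
  if (sxx < 1e-30 * length(x)) stop("degenerate regressor: x is constant")
  a <- sum((x - mean(x)) * (y - mean(y))) / sxx
  list(a = a, b = mean(y) - a * mean(x))
}

#' Grid specification for the brute-force search
#'
#' Default ranges follow the physiology of the oxy-hemoglobin response to
#' median nerve stimulation: peak-time constants of 0.1--0.6 s, shapes
#' 1--4, pure delays of 0.5--3 s. Step sizes are a package choice (the
#' ranges are prescribed, the resolution is not).
#'
#' @param tau_range,tau_step peak-time range (s) and step.
#' @param n_values integer shapes to scan.
#' @param d_range,d_step delay range (s) and step.
#' @return object of class `fit_grid` with a `candidates` data frame.
#' @export
fit_grid <- function(tau_range = c(0.1, 0.6), tau_step = 0.05,
                     n_values = 1:4, d_range = c(0.5, 3), d_step = 0.25) {
  if (diff(tau_range) < 0 || diff(d_range) < 0)
    stop("parameter ranges must be non-decreasing")
  if (tau_step <= 0 || d_step <= 0) stop("steps must be > 0")
  if (length(n_values) == 0L || any(n_values < 1))
    stop("n_values must be positive integers")
  taus <- seq(tau_range[1L], tau_range[2L], by = tau_step)
  ds <- seq(d_range[1L], d_range[2L], by = d_step)
  cand <- expand.grid(tau = taus, n = as.numeric(n_values), d = ds,
                      KEEP.OUT.ATTRS = FALSE)
  structure(list(tau_range = tau_range, tau_step = tau_step,
                 n_values = n_values, d_range = d_range, d_step = d_step,
                 candidates = cand),
            class = "fit_grid")
}

#' One stimulus epoch of paired EEG envelope and NIRS response
#'
#' @param envelope normalized EEG spectral envelope `nvc_ts` (model input).
#' @param hbo normalized NIRS oxy-hemoglobin `nvc_ts` (model output);
#'   must share `fs` and length with `envelope`.
#' @param stim_onset_s,stim_dur_s stimulus timing in seconds.
#' @param eeg_channel,nirs_channel,id identifiers.
#' @return object of class `epoch_pair`.
#' @export
epoch_pair <- function(envelope, hbo, stim_onset_s = NA_real_,
                       stim_dur_s = NA_real_, eeg_channel = NA,
                       nirs_channel = NA, id = NA) {
  stopifnot(is_nvc_ts(envelope), is_nvc_ts(hbo))
  if (abs(envelope$fs - hbo$fs) > 1e-9 ||
      length(envelope$values) != length(hbo$values))
    stop("envelope and hbo must share sampling rate and length")
  structure(list(envelope = envelope, hbo = hbo,
                 stim_onset_s = stim_onset_s, stim_dur_s = stim_dur_s,
                 eeg_channel = eeg_channel, nirs_channel = nirs_channel,
                 id = id),
            class = "epoch_pair")
}

new_fit_result <- function(params, a, b, sse, r, id = NA, n_cont = NA_real_,
                           converged = TRUE, stage = "grid") {
  structure(list(params = params, a = a, b = b, sse = sse, r = r,
                 n_continuous = n_cont, epoch_id = id,
                 converged = converged, stage = stage),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result %s> tau=%.4f n=%g d=%.4f a=%.4g b=%.4g sse=%.4g r=%.4f\n",
    x$stage, x$params$tau, x$params$n, x$params$d, x$a, x$b, x$sse, x$r))
  invisible(x)
}

# SSE of y ~ a*x+b for a matrix of candidate shapes; returns per-column
# a, b, sse (vectorised normal equations)
ols_sse_cols <- function(X, y) {
  n <- length(y)
  sy <- sum(y); syy_c <- sum(y^2) - sy^2 / n
  sx <- colSums(X)
  sxx_c <- colSums(X^2) - sx^2 / n
  sxy_c <- as.numeric(crossprod(X, y)) - sx * sy / n
  ok <- sxx_c > 1e-30 * n
  a <- ifelse(ok, sxy_c / sxx_c, 0)
  b <- (sy - a * sx) / n
  sse <- pmax(syy_c - a^2 * sxx_c, 0)
  sse[!ok] <- syy_c
  list(a = a, b = b, sse = sse)
}

# environment-level cache of kernel FFT banks keyed by (grid, fs, nfft)
.kernel_cache <- new.env(parent = emptyenv())

kernel_fft_bank <- function(grid, fs, n_sig) {
  max_len <- n_sig  # kernel support beyond the epoch never influences the fit
  nfft <- stats::nextn(n_sig + max_len, 2)
  key <- paste(digest::digest(grid$candidates), fs, nfft, sep = "|")
  hit <- .kernel_cache[[key]]
  if (!is.null(hit)) return(hit)
  cand <- grid$candidates
  K <- matrix(0 + 0i, nrow = nfft, ncol = nrow(cand))
  for (j in seq_len(nrow(cand))) {
    gp <- gamma_params(cand$tau[j], cand$n[j], cand$d[j])
    h <- gamma_kernel(gp, fs, warn_truncation = FALSE,
                      duration_s = min(gp$d + 10 * gp$n * gp$tau + 1 / fs,
                                       max_len / fs))
    K[, j] <- stats::fft(c(h, numeric(nfft - length(h))))
  }
  out <- list(nfft = nfft, K = K)
  .kernel_cache[[key]] <- out
  out
}

#' Brute-force grid fit of one epoch
#'
#' Convolves the epoch envelope with every kernel on the grid, solves gain
#' and offset by least squares for each, and returns the candidate with the
#' smallest residual sum of squares.
#'
#' @param epoch an `epoch_pair`.
#' @param grid a `fit_grid`.
#' @return `fit_result` at the best grid point.
#' @export
grid_fit <- function(epoch, grid = fit_grid()) {
  stopifnot(inherits(epoch, "epoch_pair"), inherits(grid, "fit_grid"))
  if (nrow(grid$candidates) == 0L) stop("empty parameter grid")
  g <- epoch$envelope$values
  y <- epoch$hbo$values
  fs <- epoch$envelope$fs
  n <- length(g)
  bank <- kernel_fft_bank(grid, fs, n)
  G <- stats::fft(c(g, numeric(bank$nfft - n)))
  conv <- Re(stats::mvfft(G * bank$K, inverse = TRUE))[seq_len(n), , drop = FALSE] /
    (bank$nfft * fs)
  ols <- ols_sse_cols(conv, y)
  j <- which.min(ols$sse)
  cand <- grid$candidates[j, ]
  pred <- ols$a[j] * conv[, j] + ols$b[j]
  r <- if (stats::sd(pred) > 0) stats::cor(pred, y) else 0
  new_fit_result(gamma_params(cand$tau, cand$n, cand$d),
                 a = ols$a[j], b = ols$b[j], sse = ols$sse[j], r = r,
                 id = epoch$id, n_cont = cand$n, stage = "grid")
}

# SSE objective over (tau, n, d, a, b); out-of-bound parameters are
# penalised so Nelder-Mead stays in the feasible region
epoch_sse_fn <- function(epoch) {
  g <- epoch$envelope$values
  y <- epoch$hbo$values
  fs <- epoch$envelope$fs
  n_sig <- length(g)
  nfft <- stats::nextn(2L * n_sig, 2)
  G <- stats::fft(c(g, numeric(nfft - n_sig)))
  big <- sum((y - mean(y))^2) * 1e6 + 1
  function(par) {
    tau <- par[1L]; nn <- par[2L]; d <- par[3L]; a <- par[4L]; b <- par[5L]
    viol <- max(0, 1e-3 - tau) + max(0, nn - 8) + max(0, 1 - nn) +
      max(0, -d) + max(0, d - 10) + max(0, tau - 3)
    if (viol > 0) return(big * (1 + viol))
    gp <- gamma_params(tau, nn, d)
    dur <- min(gp$d + 10 * gp$n * gp$tau + 1 / fs, n_sig / fs)
    h <- gamma_kernel(gp, fs, duration_s = dur, warn_truncation = FALSE)
    H <- stats::fft(c(h, numeric(nfft - length(h))))
    pred <- a * Re(stats::fft(G * H, inverse = TRUE))[seq_len(n_sig)] /
      (nfft * fs) + b
    sum((y - pred)^2)
  }
}

#' Simplex refinement of a grid fit
#'
#' Nelder-Mead minimisation of the residual sum of squares jointly over
#' `(tau, n, d, a, b)` from the grid solution. The shape `n` is treated as
#' continuous during refinement (gamma-function form of the kernel); the
#' result reports the continuous estimate and its nearest integer. The
#' refined SSE never exceeds the starting SSE.
#'
#' @param start `fit_result` from [grid_fit()].
#' @param epoch the `epoch_pair` that produced `start`.
#' @param maxit maximum function evaluations (default 2000).
#' @param reltol relative convergence tolerance.
#' @return refined `fit_result`; `converged` is `FALSE` when the iteration
#'   cap was hit (best-so-far parameters are still returned).
#' @export
simplex_refine <- function(start, epoch, maxit = 2000L, reltol = 1e-10) {
  stopifnot(inherits(start, "fit_result"), inherits(epoch, "epoch_pair"))
  fn <- epoch_sse_fn(epoch)
  p0 <- c(start$params$tau, start$params$n, start$params$d, start$a, start$b)
  opt <- stats::optim(p0, fn, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = reltol))
  if (opt$value <= start$sse) {
    par <- opt$par
  } else {  # monotone acceptance: never leave the start point for the worse
    par <- p0
    opt$value <- start$sse
  }
  gp_cont <- gamma_params(par[1L], par[2L], par[3L])
  pred <- forward_predict(epoch$envelope, gp_cont, par[4L], par[5L])
  r <- if (stats::sd(pred$values) > 0) stats::cor(pred$values, epoch$hbo$values) else 0
  gp_out <- gamma_params(par[1L], max(1, round(par[2L])), par[3L])
  new_fit_result(gp_out, a = par[4L], b = par[5L], sse = opt$value, r = r,
                 id = epoch$id, n_cont = par[2L],
                 converged = opt$convergence == 0, stage = "refined")
}

#' Two-step epoch fit (grid search then simplex)
#'
#' @param epoch an `epoch_pair`.
#' @param grid a `fit_grid`.
#' @param ... passed to [simplex_refine()].
#' @return refined `fit_result` with per-epoch Pearson r between predicted
#'   and observed response.
#' @export
fit_epoch <- function(epoch, grid = fit_grid(), ...) {
  simplex_refine(grid_fit(epoch, grid), epoch, ...)
}

#' Collect fit results into a data frame
#'
#' @param fits list of `fit_result`.
#' @return data frame with one row per fit.
#' @export
fits_to_df <- function(fits) {
  do.call(rbind, lapply(fits, function(f) data.frame(
    epoch_id = if (is.na(f$epoch_id)) NA else as.character(f$epoch_id),
    tau = f$params$tau, n = f$params$n, n_continuous = f$n_continuous,
    d = f$params$d, a = f$a, b = f$b, sse = f$sse, r = f$r,
    converged = f$converged, stringsAsFactors = FALSE)))
}
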