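# Shared fixtures. Small-scale simulation configs keep the unit suite
# fast; the acceptance tests use the full default configuration.

# reduced-scale config: 3 pulses, shorter records, same structure
small_sim_config <- function(seed = 1L, ...) {
  sim_config(n_pulses = 3L, seed = seed, ...)
}

# cache the expensive simulated datasets across test files
sim_cache <- new.env(parent = emptyenv())

cached_dataset <- function(key = "small", cfg = small_sim_config()) {
  hit <- sim_cache[[key]]
  if (!is.null(hit)) return(hit)
  ds <- simulate_dataset(cfg)
  sim_cache[[key]] <- ds
  ds
}

# synthetic epoch with exactly known generative parameters: smooth random
# envelope convolved with a known kernel (no noise unless asked)
make_known_epoch <- function(gp = gamma_params(0.3, 2, 2), a = 1, b = 0,
                             fs = 25, dur_s = 35, seed = 42,
                             noise_sd = 0) {
  set.seed(seed)
  raw <- stats::filter(rnorm(dur_s * fs + 100), rep(1, 50) / 50,
                       sides = 1)
  g <- nvc_ts(as.numeric(raw[101:(dur_s * fs + 100)]), fs)
  g <- nvc_ts(g$values / sd(g$values), fs)
  f <- forward_predict(g, gp, a, b)
  if (noise_sd > 0) f$values <- f$values + rnorm(length(f$values),
                                                 sd = noise_sd)
  epoch_pair(g, f, id = "known")
}

# fit results with prescribed parameter vectors and correlations, for the
# clustering tests
make_fake_fits <- function(params, rs) {
  stopifnot(nrow(params) == length(rs))
  lapply(seq_len(nrow(params)), function(i) {
    f <- list(params = gamma_params(params[i, "tau"], params[i, "n"],
                                    params[i, "d"]),
              a = params[i, "a"], b = params[i, "b"], sse = 0,
              r = rs[i], n_continuous = params[i, "n"],
              epoch_id = i, converged = TRUE, stage = "refined")
    class(f) <- "fit_result"
    f
  })
}
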