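# Orchestration: validated run configuration, the simulation recovery
# study, and the experimental-style end-to-end pipeline, all reproducible
# from (config, seed) with provenance embedded in every output.

default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    simulation = list(
      carrier_hz = 9, n_pulses = 8L, pulse_width_s = 20,
      pulse_period_s = 40, kaiser_len = 250L, kaiser_beta = 8,
      eeg_fs = 2048, nirs_fs = 25, a = 1, b = 0,
      ar_db_list = c(-Inf, 0, 4, 8, 16), nirs_noise_mod_hz = 0.5,
      trailing_rest_s = 20),
    grid = list(tau_range = c(0.1, 0.6), tau_step = 0.05,
                n_values = 1:4, d_range = c(0.5, 3), d_step = 0.25),
    preprocess = list(eeg_band = c(5, 14), eeg_order = 4L,
                      nirs_lowpass_hz = 0.5, nirs_lowpass_order = 3L,
                      chauvenet_span = 30L, smooth_window_s = 4,
                      epoch_pre_s = 5, epoch_stim_s = 15, epoch_post_s = 5,
                      r_min = 0.3, hbo_min_um = 0.5),
    cluster = list(alpha = 0.05, n_range = 2:12)
  )
}

merge_config <- function(base, user, path = "") {
  for (key in names(user)) {
    if (!key %in% names(base))
      stop(sprintf("unknown configuration key '%s%s'", path, key))
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(user[[key]]))
        stop(sprintf("configuration section '%s%s' must be a mapping", path, key))
      base[[key]] <- merge_config(base[[key]], user[[key]],
                                  paste0(path, key, "."))
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

#' Validate and normalize a run configuration
#'
#' Fills all defaults (mu band 5-14 Hz order 4; NIRS 0.5 Hz lowpass order
#' 3; Chauvenet span 30; 4 s smoothing window; 5+15+5 s epochs; grid tau
#' 0.1-0.6, n 1-4, d 0.5-3; alpha 0.05 over divisions 2-12), rejects
#' unknown keys, and checks cross-field invariants.
#'
#' @param cfg named list (possibly empty) of overrides, or a path to a
#'   YAML/JSON file containing one.
#' @return normalized configuration list of class `run_config`.
#' @export
validate_config <- function(cfg = list()) {
  if (is.character(cfg) && length(cfg) == 1L) cfg <- read_config_file(cfg)
  if (inherits(cfg, "run_config")) cfg <- unclass(cfg)
  if (!is.list(cfg)) stop("configuration must be a named list")
  full <- merge_config(default_run_config(), cfg)
  problems <- character(0)
  g <- full$grid
  if (diff(range(g$tau_range)) < 0 || g$tau_range[1] > g$tau_range[2])
    problems <- c(problems, "grid.tau_range is inverted")
  if (g$d_range[1] > g$d_range[2])
    problems <- c(problems, "grid.d_range is inverted")
  if (g$tau_step <= 0 || g$d_step <= 0)
    problems <- c(problems, "grid steps must be > 0")
  s <- full$simulation
  if (s$pulse_width_s >= s$pulse_period_s)
    problems <- c(problems, "simulation.pulse_width_s must be < pulse_period_s")
  if (s$nirs_fs <= 0 || s$eeg_fs <= 0)
    problems <- c(problems, "sampling rates must be > 0")
  p <- full$preprocess
  if (any(p$eeg_band >= s$eeg_fs / 2))
    problems <- c(problems, "preprocess.eeg_band exceeds the EEG Nyquist")
  if (full$cluster$alpha <= 0 || full$cluster$alpha >= 1)
    problems <- c(problems, "cluster.alpha must be in (0, 1)")
  if (length(problems))
    stop(paste(c("invalid configuration:", problems), collapse = "\n  - "))
  structure(full, class = "run_config")
}

read_config_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("configuration file '%s' not found", path))
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

config_sim <- function(cfg, seed = NULL) {
  s <- cfg$simulation
  do.call(sim_config, c(s, list(seed = if (is.null(seed)) cfg$seed else seed)))
}

config_grid <- function(cfg) do.call(fit_grid, cfg$grid)

provenance <- function(cfg) {
  list(config_hash = digest::digest(unclass(cfg)),
       seed = cfg$seed,
       package_version = as.character(utils::packageVersion("nvcouple")))
}

#' Simulation recovery study
#'
#' For every ground-truth kernel, amplitude ratio and epoch: simulate,
#' fit with the two-step estimator, and record the recovered parameters
#' and the Pearson correlation between predicted and simulated responses.
#' Returns the per-epoch table plus the correlation-versus-noise and
#' parameter-versus-noise summaries. Identical outputs under identical
#' (config, seed).
#'
#' @param cfg a `run_config` (see [validate_config()]); its
#'   `simulation$ar_db_list` sets the noise levels scanned.
#' @param n_seeds number of independent noise realizations per amplitude
#'   ratio (clean fits are deterministic and run once).
#' @param verbose print stage progress.
#' @return list with `fits` (per-epoch data frame), `r_vs_ar` (mean r per
#'   set and AR), `params_vs_ar` (mean recovered parameters), and
#'   `provenance`.
#' @export
run_simulation_study <- function(cfg = validate_config(), n_seeds = 1L,
                                 verbose = FALSE) {
  cfg <- validate_config(cfg)
  ds <- simulate_dataset(config_sim(cfg))
  grid <- config_grid(cfg)
  truth <- ds$ground_truth$gamma_sets
  rows <- list()
  for (k in seq_along(truth)) {
    for (ar in cfg$simulation$ar_db_list) {
      reps <- if (identical(ar, -Inf)) 1L else n_seeds
      for (rep in seq_len(reps)) {
        seed <- child_seed(cfg$seed, k * 10000 + rep * 100 +
                             match(ar, cfg$simulation$ar_db_list))
        eps <- simulated_epochs(ds, k, ar, seed = seed)
        fits <- lapply(eps, fit_epoch, grid = grid)
        df <- fits_to_df(fits)
        df$set <- k; df$ar_db <- ar; df$rep <- rep
        df$epoch <- seq_len(nrow(df))
        df$true_tau <- truth[[k]][1]
        df$true_n <- truth[[k]][2]
        df$true_d <- truth[[k]][3]
        rows[[length(rows) + 1L]] <- df
      }
      if (verbose)
        message(sprintf("set %d, AR %s dB done", k, format(ar)))
    }
  }
  fits <- do.call(rbind, rows)
  agg <- function(v) stats::aggregate(
    fits[v], by = list(set = fits$set, ar_db = fits$ar_db), FUN = mean)
  list(fits = fits,
       r_vs_ar = agg("r"),
       params_vs_ar = agg(c("tau", "n_continuous", "d", "a", "b")),
       provenance = provenance(cfg))
}

#' Experimental-style end-to-end pipeline
#'
#' Full preprocessing stream on file inputs: EEG table -> per-channel mu
#' bandpass, EMD, Hilbert envelope of IMF1, downsampling; NIRS intensity
#' table -> Chauvenet motion rejection on intensities, modified
#' Beer-Lambert law, detrend, cardiac lowpass; channel selection; epoch
#' extraction, smoothing and normalization; per-epoch two-step fits; and
#' the clustering significance scan.
#'
#' @param eeg_file delimited EEG table (first column `t`, one column per
#'   channel, header row).
#' @param nirs_file delimited intensity table (columns
#'   `<channel>_<wavelength>`, plus `t`).
#' @param events_file TSV with columns onset_s, duration_s (label
#'   optional).
#' @param cfg a `run_config`.
#' @param out_dir optional directory for intermediates (fits CSV, report
#'   JSON).
#' @param verbose print stage progress.
#' @return list with `fits` (list of `fit_result`), `fits_df`, `report`
#'   (`cluster_report` or NULL when no channels/epochs survive),
#'   `selection`, `provenance`.
#' @export
run_experimental_pipeline <- function(eeg_file, nirs_file, events_file,
                                      cfg = validate_config(),
                                      out_dir = NULL, verbose = FALSE) {
  cfg <- validate_config(cfg)
  for (f in c(eeg_file, nirs_file, events_file))
    if (!file.exists(f)) stop(sprintf("input file '%s' not found", f))
  p <- cfg$preprocess
  events <- read_events(events_file)
  eeg <- read_eeg_table(eeg_file)
  nirs <- read_nirs_table(nirs_file)
  if (verbose) message("inputs loaded: ", length(eeg$channels), " EEG channel(s), ",
                       length(nirs$channels), " NIRS channel(s), ",
                       nrow(events), " event(s)")

  envelopes <- lapply(eeg$channels, function(ch)
    spectral_envelope(ch, band = p$eeg_band, order = p$eeg_order,
                      target_fs = nirs$fs))
  hbo <- lapply(nirs$channels, function(rec) {
    clean <- apply(rec$intensities, 2, function(col) {
      cc <- chauvenet_clean(nvc_ts(col, rec$fs, rec$t0), p$chauvenet_span)
      cc$cleaned$values
    }, simplify = FALSE)
    len <- min(lengths(clean))
    rec2 <- nirs_record(vapply(clean, function(v) v[seq_len(len)],
                               numeric(len)),
                        fs = rec$fs, wavelengths_nm = rec$wavelengths_nm,
                        source_detector_mm = rec$source_detector_mm,
                        dpf = rec$dpf, extinction = rec$extinction,
                        t0 = rec$t0)
    mbll(rec2, lowpass_hz = p$nirs_lowpass_hz,
         lowpass_order = p$nirs_lowpass_order)$hbo
  })

  pulse <- events_to_pulse(events, fs = nirs$fs,
                           duration_s = ts_duration(envelopes[[1L]]))
  sel <- select_channels(envelopes, hbo, pulse, r_min = p$r_min,
                         hbo_min_um = p$hbo_min_um)
  if (verbose) message("selected ", nrow(sel$eeg), " EEG / ",
                       nrow(sel$nirs), " NIRS channel(s)")
  if (nrow(sel$eeg) == 0L || nrow(sel$nirs) == 0L) {
    warning("empty channel selection: returning an empty report")
    return(list(fits = list(), fits_df = NULL, report = NULL,
                selection = sel, provenance = provenance(cfg)))
  }

  grid <- config_grid(cfg)
  fits <- list()
  for (ech in sel$eeg$channel) for (nch in sel$nirs$channel) {
    g_ep <- extract_epochs(envelopes[[ech]], events$onset_s,
                           p$epoch_stim_s, p$epoch_pre_s, p$epoch_post_s)
    f_ep <- extract_epochs(hbo[[nch]], events$onset_s,
                           p$epoch_stim_s, p$epoch_pre_s, p$epoch_post_s)
    for (i in seq_along(g_ep)) {
      ep <- epoch_pair(smooth_normalize(g_ep[[i]], p$smooth_window_s),
                       smooth_normalize(f_ep[[i]], p$smooth_window_s),
                       stim_onset_s = events$onset_s[i],
                       stim_dur_s = events$duration_s[i],
                       eeg_channel = ech, nirs_channel = nch,
                       id = sprintf("%s_%s_ep%d", ech, nch, i))
      fits[[length(fits) + 1L]] <- fit_epoch(ep, grid)
    }
  }
  if (verbose) message(length(fits), " epoch fits done")

  report <- NULL
  if (length(fits) >= 2L) {
    fm <- build_features(fits)
    tree <- ward_linkage(fm)
    rr <- vapply(fits, function(f) f$r, numeric(1))
    n_range <- cfg$cluster$n_range
    n_range <- n_range[n_range <= length(fits)]
    report <- significance_scan(tree, rr, n_range, cfg$cluster$alpha)
  }
  fdf <- fits_to_df(fits)
  prov <- provenance(cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_delim_prov(fdf, file.path(out_dir, "fits.csv"), prov)
    if (!is.null(report))
      write_cluster_report(report, fits, file.path(out_dir, "report.json"),
                           prov)
  }
  list(fits = fits, fits_df = fdf, report = report, selection = sel,
       provenance = prov)
}

# binary pulse sequence from an event table
events_to_pulse <- function(events, fs, duration_s) {
  t <- (seq_len(round(duration_s * fs)) - 1) / fs
  on <- rep(0, length(t))
  for (i in seq_len(nrow(events))) {
    on[t >= events$onset_s[i] &
         t < events$onset_s[i] + events$duration_s[i]] <- 1
  }
  nvc_ts(on, fs, 0)
}
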