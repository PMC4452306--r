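# Delimited-text readers and writers. All files carry a one-line header;
# times are in seconds.

#' Read a delimited EEG table
#'
#' First column `t` (seconds, uniform), remaining columns one per channel.
#'
#' @param path file path (comma- or tab-delimited).
#' @return list with `channels` (named list of `nvc_ts`) and `fs`.
#' @export
read_eeg_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = guess_sep(path))
  if (!"t" %in% names(df)) stop("EEG table needs a 't' column")
  fs <- 1 / stats::median(diff(df$t))
  chans <- setdiff(names(df), "t")
  channels <- lapply(chans, function(ch) nvc_ts(df[[ch]], fs, df$t[1L]))
  names(channels) <- chans
  list(channels = channels, fs = fs)
}

#' Read a delimited NIRS intensity table
#'
#' Column `t` plus intensity columns named `<channel>_<wavelength>`
#' (e.g. `C1_690`); each channel must carry all four wavelengths.
#'
#' @param path file path.
#' @param ... passed to [nirs_record()] (optical constants).
#' @return list with `channels` (named list of `nirs_record`) and `fs`.
#' @export
read_nirs_table <- function(path, ...) {
  df <- utils::read.table(path, header = TRUE, sep = guess_sep(path))
  if (!"t" %in% names(df)) stop("NIRS table needs a 't' column")
  fs <- 1 / stats::median(diff(df$t))
  cols <- setdiff(names(df), "t")
  parts <- strsplit(cols, "_")
  ok <- lengths(parts) == 2L
  if (!all(ok)) stop("NIRS columns must be named <channel>_<wavelength>")
  chan <- vapply(parts, `[[`, "", 1L)
  wl <- as.numeric(vapply(parts, `[[`, "", 2L))
  channels <- lapply(unique(chan), function(ch) {
    idx <- which(chan == ch)
    idx <- idx[order(wl[idx])]
    nirs_record(as.matrix(df[cols[idx]]), fs = fs,
                wavelengths_nm = sort(wl[chan == ch]), t0 = df$t[1L], ...)
  })
  names(channels) <- unique(chan)
  list(channels = channels, fs = fs)
}

#' Read a stimulus-event table
#'
#' Tab-separated with header `onset_s`, `duration_s` and optional `label`.
#'
#' @param path file path.
#' @return data frame of events ordered by onset.
#' @export
read_events <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("onset_s", "duration_s")
  if (!all(need %in% names(df)))
    stop("events file needs columns onset_s and duration_s")
  df[order(df$onset_s), , drop = FALSE]
}

guess_sep <- function(path) {
  first <- readLines(path, n = 2L)
  first <- first[!startsWith(first, "#")][1L]
  if (grepl("\t", first)) "\t" else ","
}

# one-line provenance comment embedded at the top of delimited outputs;
# readers skip it (read.table's default comment.char)
provenance_line <- function(prov) {
  sprintf("# nvcouple %s seed=%s config=%s", prov$package_version,
          prov$seed, prov$config_hash)
}

write_delim_prov <- function(df, path, prov = NULL, sep = ",") {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(prov)) writeLines(provenance_line(prov), con)
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
}

#' Export a simulated dataset as delimited text files
#'
#' Writes `eeg.csv` (t, value), `envelope.csv`, one
#' `hbo_set<K>_ar<AR>.csv` per kernel and amplitude ratio, `events.tsv`
#' (onset_s, duration_s) and `ground_truth.json`.
#'
#' @param ds a `sim_dataset`.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- ds$ground_truth
  prov <- list(package_version = as.character(utils::packageVersion("nvcouple")),
               seed = cfg$seed, config_hash = digest::digest(unclass(cfg)))
  w <- function(ts, name)
    write_delim_prov(data.frame(t = ts_time(ts), value = ts$values),
                     file.path(dir, name), prov)
  w(ds$eeg, "eeg.csv")
  w(ds$envelope, "envelope.csv")
  for (k in seq_along(ds$hbo_noisy))
    for (ar in names(ds$hbo_noisy[[k]]))
      w(ds$hbo_noisy[[k]][[ar]],
        sprintf("hbo_set%d_ar%s.csv", k, gsub("-Inf", "noiseless", ar)))
  onsets <- (seq_len(cfg$n_pulses) - 1) * cfg$pulse_period_s
  write_delim_prov(
    data.frame(onset_s = onsets, duration_s = cfg$pulse_width_s,
               label = "stim"),
    file.path(dir, "events.tsv"), prov, sep = "\t")
  gt <- unclass(cfg)
  gt$ar_db_list <- ifelse(is.infinite(gt$ar_db_list), "-Inf",
                          as.character(gt$ar_db_list))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write a cluster report as JSON
#'
#' Per-division tables, the significant-cluster profile, the optimal
#' division, per-cluster mean parameters and sampled representative
#' kernels, plus provenance.
#'
#' @param report a `cluster_report`.
#' @param fits the fitted `fit_result` list the report was built from.
#' @param path output path.
#' @param provenance optional provenance list to embed.
#' @param fs kernel sampling rate.
#' @return invisibly, the path.
#' @export
write_cluster_report <- function(report, fits, path, provenance = NULL,
                                 fs = 25) {
  opt <- select_optimal(report)
  reps <- if (!is.na(opt))
    representative_kernels(report$labels[[as.character(opt)]], fits, fs)
  else NULL
  payload <- list(
    divisions = report$divisions,
    significant_counts = as.list(report$cs),
    optimal_division = if (is.na(opt)) NULL else opt,
    representative = lapply(reps, function(rk)
      list(params = rk$params, n_continuous = rk$n_continuous,
           size = rk$size, kernel_fs = rk$kernel$fs,
           kernel = rk$kernel$values)),
    alpha = report$alpha,
    p_values_approximate = report$p_values_approximate,
    provenance = provenance)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Write epoch pairs as delimited files
#'
#' One CSV per epoch, named `epoch_<eeg>_<nirs>_<index>.csv`, with columns
#' `t`, `envelope`, `hbo` and a comment line carrying the stimulus timing.
#'
#' @param epochs list of `epoch_pair`.
#' @param dir output directory (created if missing).
#' @return invisibly, the files written.
#' @export
write_epochs <- function(epochs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(epochs), function(i) {
    ep <- epochs[[i]]
    stopifnot(inherits(ep, "epoch_pair"))
    path <- file.path(dir, sprintf("epoch_%s_%s_%03d.csv",
                                   ep$eeg_channel, ep$nirs_channel, i))
    con <- file(path, "w")
    writeLines(sprintf("# onset_s=%g duration_s=%g eeg=%s nirs=%s",
                       ep$stim_onset_s, ep$stim_dur_s, ep$eeg_channel,
                       ep$nirs_channel), con)
    utils::write.table(data.frame(t = ts_time(ep$envelope),
                                  envelope = ep$envelope$values,
                                  hbo = ep$hbo$values),
                       con, sep = ",", row.names = FALSE, quote = FALSE)
    close(con)
    path
  }, character(1))
  invisible(paths)
}

#' Read epoch pairs written by [write_epochs()]
#'
#' @param dir directory containing `epoch_*.csv` files.
#' @return list of `epoch_pair`.
#' @export
read_epochs <- function(dir) {
  files <- sort(list.files(dir, pattern = "^epoch_.*\\.csv$",
                           full.names = TRUE))
  if (length(files) == 0L) stop("no epoch files found in ", dir)
  lapply(files, function(path) {
    meta <- readLines(path, n = 1L)
    gv <- function(key) sub(sprintf(".*%s=([^ ]+).*", key), "\\1", meta)
    df <- utils::read.table(path, header = TRUE, sep = ",")
    fs <- 1 / stats::median(diff(df$t))
    epoch_pair(nvc_ts(df$envelope, fs, df$t[1L]),
               nvc_ts(df$hbo, fs, df$t[1L]),
               stim_onset_s = as.numeric(gv("onset_s")),
               stim_dur_s = as.numeric(gv("duration_s")),
               eeg_channel = gv("eeg"), nirs_channel = gv("nirs"),
               id = sub("\\.csv$", "", basename(path)))
  })
}
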