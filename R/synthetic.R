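# Synthetic dHbO generator: class-conditional double-gamma hemodynamic
# responses on a subset of informative channels, white noise, heavy sporadic
# outliers, per-subject gain variability. Emulates the shape and summary
# statistics of the 14-subject, 10-trial, 27-channel, 10 Hz fear-detection
# recordings the pipeline targets; it is validated by construction, not
# against any real recording.

#' Parameters of the canonical double-gamma HRF
#'
#' @param peak_time Seconds to the response peak (default 6).
#' @param undershoot_time Seconds to the undershoot peak (default 16).
#' @param undershoot_ratio Relative undershoot amplitude (default 1/6).
#' @param onset_delay Seconds between stimulus and response onset (default
#'   3, matching the start of the analysis window).
#' @return An object of class `hrf_params`.
#' @export
hrf_params <- function(peak_time = 6, undershoot_time = 16,
                       undershoot_ratio = 1 / 6, onset_delay = 3) {
  stopifnot(peak_time < undershoot_time, undershoot_ratio > 0)
  structure(list(peak_time = peak_time, undershoot_time = undershoot_time,
                 undershoot_ratio = undershoot_ratio,
                 onset_delay = onset_delay),
            class = "hrf_params")
}

#' Sampled double-gamma hemodynamic response kernel
#'
#' Difference of two gamma densities (response minus scaled undershoot),
#' delayed by `onset_delay` and peak-normalized to 1, sampled over the trial
#' duration. The value at t = 0 is 0 and the maximum sits at
#' `onset_delay + peak_time` up to one sample.
#'
#' @param params An [hrf_params()] object.
#' @param sampling_rate Samples per second (default 10).
#' @param duration Kernel length in seconds (default 30).
#' @return Numeric vector of `duration * sampling_rate` samples.
#' @export
hrf_kernel <- function(params = hrf_params(), sampling_rate = 10,
                       duration = 30) {
  stopifnot(inherits(params, "hrf_params"))
  t <- seq(0, duration - 1 / sampling_rate, by = 1 / sampling_rate)
  tt <- t - params$onset_delay
  g <- function(x, peak) ifelse(x > 0, stats::dgamma(x, shape = peak + 1,
                                                     rate = 1), 0)
  h <- g(tt, params$peak_time) -
    params$undershoot_ratio * g(tt, params$undershoot_time)
  h / max(h)
}

#' Configuration of the synthetic dHbO generator
#'
#' Defaults mirror the balanced 14-subject design the pipeline targets:
#' 10 trials per subject (5 fear / 5 non-fear, alternating so the first six
#' trials are 3/3), 27 channels at 10 Hz, 30 s trials. Fear trials add an
#' HRF-shaped deflection of `effect_amplitude` (dHbO units, scaled by a
#' per-subject gain) to the informative channels; all channels carry white
#' noise and a small fraction of samples are replaced by heavy outliers,
#' exercising the robustness of the median/IQR-arctangent scaler.
#'
#' @param n_subjects,n_trials,n_channels,sampling_rate,trial_duration Design
#'   shape (defaults 14, 10, 27, 10 Hz, 30 s).
#' @param informative_channels 1-based channel labels carrying the class
#'   effect.
#' @param effect_amplitude Peak fear response in dHbO units.
#' @param noise_sd White-noise standard deviation.
#' @param outlier_rate Fraction of samples replaced by outliers.
#' @param outlier_scale Outlier magnitude as a multiple of `noise_sd`.
#' @param subject_variability_sd SD of the per-subject multiplicative gain.
#' @param seed Integer seed; the dataset is fully determined by it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 14L, n_trials = 10L,
                         n_channels = 27L, sampling_rate = 10,
                         trial_duration = 30,
                         informative_channels = c(8L, 9L, 10L),
                         effect_amplitude = 1, noise_sd = 0.3,
                         outlier_rate = 0.005, outlier_scale = 50,
                         subject_variability_sd = 0.2, seed = 1L) {
  if (n_trials %% 2L != 0L) stop("n_trials must be even (balanced labels)")
  if (outlier_rate < 0 || outlier_rate > 1)
    stop("outlier_rate must lie in [0, 1]")
  if (length(informative_channels) &&
      !all(informative_channels %in% seq_len(n_channels)))
    stop("informative_channels must be a subset of 1..n_channels")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials = as.integer(n_trials),
                 n_channels = as.integer(n_channels),
                 sampling_rate = sampling_rate,
                 trial_duration = trial_duration,
                 informative_channels = as.integer(informative_channels),
                 effect_amplitude = effect_amplitude, noise_sd = noise_sd,
                 outlier_rate = outlier_rate, outlier_scale = outlier_scale,
                 subject_variability_sd = subject_variability_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Simulate a synthetic dHbO trial set
#'
#' @param config A [synth_config()].
#' @return A [trial_set()] (marked `synthetic`) with the generating
#'   configuration attached as attribute `config`.
#' @examples
#' ts <- simulate_dataset(synth_config(n_subjects = 2, seed = 7))
#' dim(ts$signals)
#' @export
simulate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  S <- config$n_subjects; Tr <- config$n_trials; C <- config$n_channels
  L <- as.integer(config$trial_duration * config$sampling_rate)
  hrf <- hrf_kernel(hrf_params(), config$sampling_rate,
                    config$trial_duration)
  # alternating labels keep the first six trials balanced 3/3 for the
  # subject-dependent split
  lab_row <- rep(c("fear", "non-fear"), length.out = Tr)
  labels <- matrix(rep(lab_row, each = S), S, Tr)
  signals <- array(rnorm(S * Tr * C * L, sd = config$noise_sd),
                   c(S, Tr, C, L))
  gains <- 1 + rnorm(S, sd = config$subject_variability_sd)
  if (length(config$informative_channels) && config$effect_amplitude != 0) {
    effect <- outer(rep(1, length(config$informative_channels)), hrf)
    for (s in seq_len(S)) for (tr in which(lab_row == "fear"))
      signals[s, tr, config$informative_channels, ] <-
        signals[s, tr, config$informative_channels, ] +
        config$effect_amplitude * gains[s] * effect
  }
  if (config$outlier_rate > 0) {
    hit <- which(runif(length(signals)) < config$outlier_rate)
    signals[hit] <- rnorm(length(hit),
                          sd = config$noise_sd * config$outlier_scale)
  }
  out <- trial_set(signals, labels, sampling_rate = config$sampling_rate,
                   synthetic = TRUE)
  attr(out, "config") <- config
  out
}

# ---- plain-text dataset I/O ----------------------------------------------

#' Write a trial set as a plain-text dataset directory
#'
#' One tab-separated file per subject (rows = samples of all trials stacked,
#' columns = 1-based channel headers `ch1..chC`) plus a `manifest.tsv`
#' listing subject ID, file, trial boundaries (1-based start/end rows) and
#' labels, with header comment lines carrying the sampling rate, channel
#' count and a synthetic-data marker.
#'
#' @param trials A [trial_set()].
#' @param path Directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(trials, path) {
  stopifnot(inherits(trials, "trial_set"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- dim(trials$signals)
  man <- NULL
  for (s in seq_len(d[1])) {
    id <- trials$subject_ids[s]
    fn <- sprintf("subject_%s.tsv", id)
    block <- do.call(rbind, lapply(seq_len(d[2]), function(tr)
      t(trials$signals[s, tr, , ])))
    colnames(block) <- paste0("ch", seq_len(d[3]))
    write.table(format(block, digits = 17, trim = TRUE, scientific = TRUE),
                file.path(path, fn), sep = "\t", quote = FALSE,
                row.names = FALSE)
    man <- rbind(man, data.frame(
      subject = id, file = fn, trial = seq_len(d[2]),
      start = (seq_len(d[2]) - 1L) * d[4] + 1L,
      end = seq_len(d[2]) * d[4],
      label = trials$labels[s, ], stringsAsFactors = FALSE))
  }
  con <- file(file.path(path, "manifest.tsv"), "w")
  writeLines(c(sprintf("# sampling_rate %g", trials$sampling_rate),
               sprintf("# n_channels %d", d[3]),
               sprintf("# synthetic %s", isTRUE(trials$synthetic))), con)
  suppressWarnings(
    write.table(man, con, sep = "\t", quote = FALSE, row.names = FALSE))
  close(con)
  invisible(path)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' Validates the manifest against the signal files: channel headers must
#' match the declared channel count, every trial must span the same number
#' of samples, and labels must be balanced within each subject.
#'
#' @param path Dataset directory.
#' @return A [trial_set()].
#' @export
read_dataset <- function(path) {
  mf <- file.path(path, "manifest.tsv")
  if (!file.exists(mf)) stop("no manifest.tsv found in ", path)
  hdr <- readLines(mf)
  hdr <- hdr[startsWith(hdr, "#")]
  getv <- function(key) {
    ln <- hdr[grepl(paste0("^# ", key, " "), hdr)]
    if (!length(ln)) stop("manifest missing header field ", key)
    sub(paste0("^# ", key, " "), "", ln[1])
  }
  fs <- as.numeric(getv("sampling_rate"))
  C <- as.integer(getv("n_channels"))
  synthetic <- identical(getv("synthetic"), "TRUE")
  man <- read.table(mf, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  need <- c("subject", "file", "trial", "start", "end", "label")
  if (!all(need %in% names(man)))
    stop("malformed manifest: need columns ", paste(need, collapse = ", "))
  subjects <- unique(man$subject)
  lens <- unique(man$end - man$start + 1L)
  if (length(lens) != 1L) stop("trials have inconsistent lengths")
  L <- lens
  n_trials <- unique(table(man$subject))
  if (length(n_trials) != 1L)
    stop("subjects have inconsistent trial counts")
  signals <- array(0, c(length(subjects), n_trials, C, L))
  labels <- matrix("", length(subjects), n_trials)
  for (s in seq_along(subjects)) {
    rows <- man[man$subject == subjects[s], , drop = FALSE]
    rows <- rows[order(rows$trial), , drop = FALSE]
    dat <- read.table(file.path(path, rows$file[1]), header = TRUE,
                      sep = "\t")
    if (ncol(dat) != C)
      stop(sprintf("subject %s: %d channel columns, manifest declares %d",
                   subjects[s], ncol(dat), C))
    if (!identical(names(dat), paste0("ch", seq_len(C))))
      stop(sprintf("subject %s: channel headers must be ch1..ch%d",
                   subjects[s], C))
    if (nrow(dat) < max(rows$end))
      stop(sprintf("subject %s: file has %d rows, manifest needs %d",
                   subjects[s], nrow(dat), max(rows$end)))
    for (tr in seq_len(nrow(rows))) {
      signals[s, tr, , ] <- t(as.matrix(dat[rows$start[tr]:rows$end[tr], ]))
      labels[s, tr] <- rows$label[tr]
    }
  }
  trial_set(signals, labels, subject_ids = subjects, sampling_rate = fs,
            synthetic = synthetic)
}

#' Deterministic toy fixtures
#'
#' Small hand-checkable objects used in examples and tests: a Bell-state
#' circuit (RY(pi/2) then CNOT, amplitudes \eqn{(1/\sqrt2, 0, 0, 1/\sqrt2)})
#' and a 2-subject, 4-trial micro dataset that runs the full pipeline in
#' seconds (2 x 4 x 12 = 96 windows).
#'
#' @return A list with `bell_circuit`, `bell_amplitudes` and
#'   `micro_dataset`.
#' @export
toy_fixtures <- function() {
  bell <- qcircuit(2, list(gate_spec("RY", 0, pi / 2),
                           gate_spec("CNOT", c(0, 1))), readout = 0:1)
  micro <- simulate_dataset(synth_config(
    n_subjects = 2L, n_trials = 4L, informative_channels = c(5L, 6L),
    effect_amplitude = 2, noise_sd = 0.3, seed = 42L))
  list(bell_circuit = bell,
       bell_amplitudes = c(1, 0, 0, 1) / sqrt(2),
       micro_dataset = micro)
}
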