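# Trial windowing, robust median/IQR + arctangent scaling, embedding-range
# mapping and Pearson channel pruning.

#' Labelled fNIRS trial set
#'
#' Container for dHbO trials organized as subjects x trials x channels x
#' time. Labels are `"fear"` / `"non-fear"` and must be balanced within each
#' subject.
#'
#' @param signals Numeric 4-d array (subjects x trials x channels x samples).
#' @param labels Character matrix (subjects x trials) of `"fear"` /
#'   `"non-fear"`.
#' @param subject_ids Optional subject identifiers (default `S1..Sn`).
#' @param sampling_rate Samples per second (default 10).
#' @param synthetic Logical flag marking generated data.
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(signals, labels, subject_ids = NULL,
                      sampling_rate = 10, synthetic = FALSE) {
  stopifnot(is.array(signals), length(dim(signals)) == 4L)
  d <- dim(signals)
  labels <- as.matrix(labels)
  if (!all(dim(labels) == d[1:2]))
    stop("labels must be a subjects x trials matrix matching the signals")
  if (!all(labels %in% c("fear", "non-fear")))
    stop("labels must be 'fear' or 'non-fear'")
  nf <- rowSums(labels == "fear")
  if (any(nf * 2L != d[2]))
    stop(sprintf("unbalanced labels for subject(s) %s",
                 paste(which(nf * 2L != d[2]), collapse = ", ")))
  subject_ids <- subject_ids %||% paste0("S", seq_len(d[1]))
  stopifnot(length(subject_ids) == d[1])
  structure(list(signals = signals, labels = labels,
                 subject_ids = as.character(subject_ids),
                 sampling_rate = sampling_rate, synthetic = synthetic),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$signals)
  cat(sprintf(
    "<trial_set: %d subjects x %d trials, %d channels, %d samples @ %g Hz%s>\n",
    d[1], d[2], d[3], d[4], x$sampling_rate,
    if (isTRUE(x$synthetic)) ", synthetic" else ""))
  invisible(x)
}

#' Restrict trials to the post-stimulus analysis window
#'
#' Keeps the segment between 3 and 15 seconds after stimulus onset — the
#' period in which the hemodynamic response is expected — using 0-based
#' sample indexing and a half-open interval: samples `[30, 150)` at 10 Hz,
#' i.e. the sample at 3.0 s is included and the one at 15.0 s excluded.
#'
#' @param trials A [trial_set()] with trials at least 15 s long.
#' @param t_start,t_end Window bounds in seconds.
#' @return A [trial_set()] with `(t_end - t_start) * sampling_rate` samples
#'   per trial.
#' @export
extract_analysis_window <- function(trials, t_start = 3, t_end = 15) {
  stopifnot(inherits(trials, "trial_set"))
  fs <- trials$sampling_rate
  i0 <- round(t_start * fs)
  i1 <- round(t_end * fs)
  if (dim(trials$signals)[4] < i1)
    stop(sprintf("trials have %d samples; need at least %d (%g s at %g Hz)",
                 dim(trials$signals)[4], i1, t_end, fs))
  trials$signals <- trials$signals[, , , (i0 + 1L):i1, drop = FALSE]
  trials
}

#' Cut trials into non-overlapping windows
#'
#' Partitions each trial into consecutive disjoint windows of `window_len`
#' samples (12 windows of 10 samples for the 3-15 s segment at 10 Hz);
#' concatenating the windows reconstructs the trial exactly. Labels are
#' inherited from the trial.
#'
#' @param trials A [trial_set()] whose trial length is divisible by
#'   `window_len`.
#' @param window_len Samples per window (default 10).
#' @return An object of class `window_set`: a list with `x` (windows x
#'   channels x window_len array), `meta` (data.frame: `subject`, `trial`,
#'   `window`, `label`), `channels` (1-based channel labels) and
#'   `sampling_rate`.
#' @export
make_windows <- function(trials, window_len = 10L) {
  stopifnot(inherits(trials, "trial_set"))
  d <- dim(trials$signals)
  if (d[4] %% window_len != 0L)
    stop(sprintf("trial length %d is not divisible by window length %d",
                 d[4], window_len))
  n_win <- d[4] %/% window_len
  N <- d[1] * d[2] * n_win
  x <- array(0, c(N, d[3], window_len))
  meta <- data.frame(subject = character(N), trial = integer(N),
                     window = integer(N), label = character(N),
                     stringsAsFactors = FALSE)
  i <- 0L
  for (s in seq_len(d[1])) for (tr in seq_len(d[2])) for (w in seq_len(n_win)) {
    i <- i + 1L
    x[i, , ] <- trials$signals[s, tr, , (w - 1L) * window_len + seq_len(window_len)]
    meta$subject[i] <- trials$subject_ids[s]
    meta$trial[i] <- tr
    meta$window[i] <- w
    meta$label[i] <- trials$labels[s, tr]
  }
  structure(list(x = x, meta = meta, channels = seq_len(d[3]),
                 sampling_rate = trials$sampling_rate),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set: %d windows x %d channels x %d samples>\n",
              dim(x$x)[1], dim(x$x)[2], dim(x$x)[3]))
  invisible(x)
}

#' Subset a window set by window index
#'
#' @param ws A [make_windows()] result.
#' @param idx Integer window indices to keep.
#' @return A `window_set` restricted to `idx`.
#' @export
subset_windows <- function(ws, idx) {
  stopifnot(inherits(ws, "window_set"))
  ws$x <- ws$x[idx, , , drop = FALSE]
  ws$meta <- ws$meta[idx, , drop = FALSE]
  rownames(ws$meta) <- NULL
  ws
}

#' Keep only the given channels of a window set
#'
#' @param ws A `window_set`.
#' @param keep Channel labels (1-based, as in `ws$channels`) to keep.
#' @return A `window_set` with the channel dimension restricted to `keep`.
#' @export
select_window_channels <- function(ws, keep) {
  stopifnot(inherits(ws, "window_set"), all(keep %in% ws$channels))
  pos <- match(keep, ws$channels)
  ws$x <- ws$x[, pos, , drop = FALSE]
  ws$channels <- ws$channels[pos]
  ws
}

#' Fit the robust scaler on training windows
#'
#' Computes the quartiles Q1, Q2 (median) and Q3 per channel, pooling all
#' training samples of that channel (time points within a channel share the
#' optode's scale). Quantiles use linear interpolation between order
#' statistics (R's default type 7). The interquartile range must be positive
#' on every channel.
#'
#' @param training_windows A `window_set` restricted to training folds only.
#' @return An object of class `robust_scaler`: data.frame with `channel`,
#'   `q1`, `q2`, `q3`.
#' @export
fit_robust_scaler <- function(training_windows) {
  stopifnot(inherits(training_windows, "window_set"))
  if (dim(training_windows$x)[1] < 1L) stop("empty training set")
  C <- dim(training_windows$x)[2]
  qs <- t(vapply(seq_len(C), function(ch)
    quantile(training_windows$x[, ch, ], c(0.25, 0.5, 0.75), names = FALSE),
    numeric(3)))
  iqr <- qs[, 3] - qs[, 1]
  if (any(iqr <= 0))
    stop(sprintf("degenerate channel(s) with zero interquartile range: %s",
                 paste(training_windows$channels[iqr <= 0], collapse = ", ")))
  structure(data.frame(channel = training_windows$channels,
                       q1 = qs[, 1], q2 = qs[, 2], q3 = qs[, 3]),
            class = c("robust_scaler", "data.frame"))
}

#' Robust median/IQR scaling with arctangent squashing
#'
#' Elementwise \eqn{x_{scaled} = \arctan((x - Q_2) / (Q_3 - Q_1))} per
#' channel. The median/IQR location-scale step bounds the influence of
#' outliers and the arctangent maps any real input strictly into
#' \eqn{(-\pi/2, \pi/2)}; the transform is monotone in `x`.
#'
#' @param x A `window_set`, a (windows x channels x samples) array, or a
#'   numeric vector (single-channel scaler only).
#' @param params A [fit_robust_scaler()] result fitted on training data.
#' @return Scaled data of the same shape/class as `x`.
#' @export
apply_robust_arctan <- function(x, params) {
  stopifnot(inherits(params, "robust_scaler"))
  scale1 <- function(v, ch) atan((v - params$q2[ch]) /
                                 (params$q3[ch] - params$q1[ch]))
  if (inherits(x, "window_set")) {
    stopifnot(identical(as.integer(x$channels), as.integer(params$channel)))
    for (ch in seq_along(x$channels))
      x$x[, ch, ] <- scale1(x$x[, ch, ], ch)
    x
  } else if (is.array(x) && length(dim(x)) == 3L) {
    stopifnot(dim(x)[2] == nrow(params))
    for (ch in seq_len(dim(x)[2]))
      x[, ch, ] <- scale1(x[, ch, ], ch)
    x
  } else if (is.numeric(x)) {
    stopifnot(nrow(params) == 1L)
    scale1(x, 1L)
  } else stop("unsupported input type")
}

#' Map arctangent-scaled values onto the angle-embedding range
#'
#' The RY angle embedding expects inputs in \eqn{[0, \pi]}; since the scaled
#' values live in \eqn{(-\pi/2, \pi/2)}, the unique order-preserving shift
#' (no stretch) is \eqn{x \mapsto x + \pi/2}.
#'
#' @param x Numeric data in \eqn{(-\pi/2, \pi/2)}.
#' @return `x + pi/2`, in \eqn{(0, \pi)}.
#' @export
rescale_to_embedding_range <- function(x) {
  v <- if (inherits(x, "window_set")) x$x else x
  if (any(v <= -pi / 2 | v >= pi / 2))
    stop("values must lie strictly inside (-pi/2, pi/2); apply the robust arctan scaler first")
  if (inherits(x, "window_set")) {
    x$x <- x$x + pi / 2
    x
  } else x + pi / 2
}

#' Prune channels by Pearson correlation with the class label
#'
#' Scores every channel by the mean over its within-window time points of
#' the absolute Pearson correlation between that feature and the binary
#' label (fear = 1) across all training windows, and drops the `n_drop`
#' lowest-scoring channels. Constant features contribute a score of 0. Ties
#' are broken deterministically: the lower channel label is dropped first.
#'
#' @param windows A training `window_set` with both classes present.
#' @param n_drop Number of channels to drop (default 2, reducing the
#'   27-channel x 10-sample window to 250 features for the 8-qubit amplitude
#'   embedding).
#' @return A list with `keep` and `drop` (1-based channel labels) and
#'   `scores` (named per-channel score vector).
#' @export
select_channels_pearson <- function(windows, n_drop = 2L) {
  stopifnot(inherits(windows, "window_set"))
  y <- as.numeric(windows$meta$label == "fear")
  if (length(unique(y)) < 2L) stop("both classes required for channel scoring")
  C <- dim(windows$x)[2]
  if (C < n_drop + 1L) stop("cannot drop that many channels")
  Tn <- dim(windows$x)[3]
  scores <- vapply(seq_len(C), function(ch) {
    r <- vapply(seq_len(Tn), function(t) {
      v <- windows$x[, ch, t]
      if (sd(v) == 0) 0 else abs(cor(v, y))
    }, numeric(1))
    mean(r)
  }, numeric(1))
  names(scores) <- windows$channels
  ord <- order(scores, windows$channels)  # ties: lower label dropped first
  drop <- sort(windows$channels[ord[seq_len(n_drop)]])
  keep <- setdiff(windows$channels, drop)
  list(keep = keep, drop = drop, scores = scores)
}

#' Flatten a channels x samples window into a feature vector
#'
#' Channel-major order: channel 1's samples 1-10 first, then channel 2, and
#' so on. A 25 x 10 window (after pruning 2 of 27 channels) gives the
#' 250-feature vector the AEPQC amplitude embedding expects; the inverse is
#' [unflatten_window()].
#'
#' @param window Numeric matrix (channels x 10).
#' @return Numeric vector of length `10 * nrow(window)`.
#' @export
flatten_for_aepqc <- function(window) {
  window <- as.matrix(window)
  if (ncol(window) != 10L)
    stop(sprintf("expected 10 samples per channel, got %d", ncol(window)))
  as.vector(t(window))
}

#' Invert [flatten_for_aepqc()]
#'
#' @param v Flat feature vector (length divisible by 10).
#' @param n_channels Number of channels.
#' @return A channels x 10 matrix.
#' @export
unflatten_window <- function(v, n_channels) {
  if (length(v) != 10L * n_channels)
    stop("length does not match n_channels x 10")
  matrix(v, nrow = n_channels, byrow = TRUE)
}
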