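# ERP chain: epoch container, filtering, segmentation, baseline correction,
# mastoid re-referencing, artifact rejection, averaging, LPP peak extraction
# and frontal-asymmetry valence classification.
#
# Fixed pipeline order: lowpass -> notch -> segment -> baseline ->
# rereference -> reject -> average -> peak. Filtering before segmentation
# avoids epoch-edge transients; baseline before re-referencing keeps the
# constant-offset removal independent of reference noise.

#' Default recording montage
#'
#' Eight scalp channels (frontal poles, lateral/midline frontal, central and
#' parietal midline) plus the two mastoid references.
#'
#' @return Character vector of channel names.
#' @export
default_montage <- function() {
  c("Fp1", "Fpz", "Fp2", "F3", "F4", "Fz", "Cz", "Pz", "M1", "M2")
}

mastoid_channels <- function() c("M1", "M2")

#' Multichannel EEG epoch container
#'
#' @param data Numeric array indexed `(trial, channel, sample)`, voltages in
#'   microvolts. A `channel x sample` matrix is promoted to a single trial.
#' @param fs Sampling rate in Hz.
#' @param t0 Time of the first sample in ms relative to stimulus onset
#'   (default -200).
#' @param channels Channel names, length `dim(data)[2]`.
#' @param condition Per-trial condition label (`like` / `neutral` /
#'   `dislike` in the reference design), length `dim(data)[1]`.
#' @return Object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, t0 = -200, channels, condition = NULL) {
  if (is.matrix(data)) data <- array(data, c(1L, nrow(data), ncol(data)))
  stopifnot(is.array(data), length(dim(data)) == 3L, is.numeric(fs), fs > 0)
  nd <- dim(data)
  if (length(channels) != nd[2]) {
    stop("channels has length ", length(channels), " but data has ", nd[2],
         " channel rows", call. = FALSE)
  }
  if (is.null(condition)) condition <- rep("unlabeled", nd[1])
  if (length(condition) == 1L) condition <- rep(condition, nd[1])
  if (length(condition) != nd[1]) {
    stop("condition has length ", length(condition), " but data has ", nd[1],
         " trials", call. = FALSE)
  }
  dimnames(data) <- list(NULL, channels, NULL)
  structure(list(data = data, fs = fs, t0 = t0,
                 channels = as.character(channels),
                 condition = as.character(condition)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  nd <- dim(x$data)
  cat("<epoch_set> ", nd[1], " trials x ", nd[2], " channels x ", nd[3],
      " samples @ ", x$fs, " Hz, t0 = ", x$t0, " ms\n", sep = "")
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  cat("  conditions:", paste(names(table(x$condition)), table(x$condition),
                             sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' Continuous multichannel EEG recording
#'
#' @param data Numeric `channel x sample` matrix in microvolts.
#' @param fs Sampling rate in Hz.
#' @param channels Channel names, length `nrow(data)`.
#' @return Object of class `continuous_eeg`.
#' @export
continuous_eeg <- function(data, fs, channels) {
  stopifnot(is.matrix(data), is.numeric(fs), fs > 0,
            length(channels) == nrow(data))
  rownames(data) <- channels
  structure(list(data = data, fs = fs, channels = as.character(channels)),
            class = "continuous_eeg")
}

#' Epoch time axis in ms
#'
#' @param x An `epoch_set` or `erp_waveform`.
#' @return Numeric vector of per-sample times in ms relative to onset.
#' @export
epoch_times <- function(x) {
  ns <- if (inherits(x, "epoch_set")) dim(x$data)[3] else ncol(x$data)
  x$t0 + (seq_len(ns) - 1L) * 1000 / x$fs
}

# apply a zero-phase filter to every series of an epoch_set / continuous_eeg
apply_zerophase <- function(x, b, a) {
  if (inherits(x, "continuous_eeg")) {
    x$data <- t(apply(x$data, 1L, filtfilt, b = b, a = a))
    rownames(x$data) <- x$channels
    return(x)
  }
  nd <- dim(x$data)
  for (tr in seq_len(nd[1])) {
    for (ch in seq_len(nd[2])) {
      x$data[tr, ch, ] <- filtfilt(x$data[tr, ch, ], b, a)
    }
  }
  x
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies a zero-phase (forward-backward) Butterworth low-pass per trial and
#' channel. DC is preserved; the effective magnitude response is the squared
#' single-pass response.
#'
#' @param x An `epoch_set` or `continuous_eeg`.
#' @param cutoff Cutoff frequency in Hz (default 30); must be below Nyquist.
#' @param order Butterworth order of the single pass (default 4).
#' @return Filtered object of the same class.
#' @export
lowpass <- function(x, cutoff = 30, order = 4L) {
  UseMethod("lowpass")
}

#' @export
lowpass.epoch_set <- function(x, cutoff = 30, order = 4L) {
  co <- butter_lowpass(order, cutoff, x$fs)
  apply_zerophase(x, co$b, co$a)
}

#' @export
lowpass.continuous_eeg <- lowpass.epoch_set

#' Zero-phase power-line notch filter
#'
#' Biquad notch at `freq` Hz (default 50) applied forward-backward per trial
#' and channel.
#'
#' @inheritParams lowpass
#' @param freq Notch center in Hz.
#' @param q Quality factor (bandwidth `freq/q`), default 30.
#' @return Filtered object of the same class.
#' @export
notch <- function(x, freq = 50, q = 30) {
  UseMethod("notch")
}

#' @export
notch.epoch_set <- function(x, freq = 50, q = 30) {
  co <- notch_coefs(freq, x$fs, q)
  apply_zerophase(x, co$b, co$a)
}

#' @export
notch.continuous_eeg <- notch.epoch_set

#' Cut stimulus-locked epochs from a continuous recording
#'
#' Extracts one epoch per event over `window` (ms, default -200..800). The
#' boundary convention is half-open: the sample at the event time belongs to
#' the post-stimulus side, so a 1000 ms window at `fs` Hz yields exactly
#' `fs` samples (at 500 Hz: samples at -200, -198, ..., 798 ms). Events whose
#' window exceeds the recording are dropped and listed in the
#' `"dropped_events"` attribute.
#'
#' @param x A `continuous_eeg`.
#' @param events Integer sample indices (1-based) of stimulus onsets.
#' @param window Length-2 window in ms around each event.
#' @param condition Optional per-event condition labels.
#' @return An `epoch_set` with `t0 = window[1]`; attribute `dropped_events`
#'   holds the onset samples of rejected events.
#' @export
segment <- function(x, events, window = c(-200, 800), condition = NULL) {
  stopifnot(inherits(x, "continuous_eeg"), window[1] < 0, window[2] > 0)
  events <- as.integer(events)
  if (!is.null(condition) && length(condition) != length(events)) {
    stop("condition must have one label per event", call. = FALSE)
  }
  n_pre <- round(x$fs * -window[1] / 1000)
  n_post <- round(x$fs * window[2] / 1000)
  ns_rec <- ncol(x$data)
  first <- events - n_pre
  last <- events + n_post - 1L
  ok <- first >= 1L & last <= ns_rec
  dropped <- events[!ok]
  keep <- which(ok)
  n_len <- n_pre + n_post
  data <- array(NA_real_, c(length(keep), nrow(x$data), n_len))
  for (i in seq_along(keep)) {
    data[i, , ] <- x$data[, first[keep[i]]:last[keep[i]]]
  }
  ep <- epoch_set(data, fs = x$fs, t0 = window[1], channels = x$channels,
                  condition = if (is.null(condition)) NULL else condition[keep])
  attr(ep, "dropped_events") <- dropped
  ep
}

#' Constant baseline correction
#'
#' Subtracts, per trial and channel, the mean voltage over the baseline
#' window (default the full pre-stimulus interval -200..0 ms, endpoints
#' inclusive).
#'
#' @param x An `epoch_set`.
#' @param window Baseline window in ms.
#' @return Baseline-corrected `epoch_set`.
#' @export
baseline_correct <- function(x, window = c(-200, 0)) {
  stopifnot(inherits(x, "epoch_set"))
  tt <- epoch_times(x)
  idx <- which(tt >= window[1] & tt <= window[2])
  if (!length(idx)) stop("baseline window outside epoch span", call. = FALSE)
  bl <- apply(x$data[, , idx, drop = FALSE], c(1L, 2L), mean)
  x$data <- x$data - as.vector(bl)  # recycles over the sample dimension
  x
}

#' Re-reference to averaged mastoids
#'
#' Subtracts the per-sample mean of the two mastoid channels from every
#' channel.
#'
#' @param x An `epoch_set`.
#' @param ref_channels Names of the two reference channels (default
#'   `c("M1", "M2")`).
#' @return Re-referenced `epoch_set`.
#' @export
rereference <- function(x, ref_channels = mastoid_channels()) {
  stopifnot(inherits(x, "epoch_set"))
  ri <- match(ref_channels, x$channels)
  if (anyNA(ri)) {
    stop("reference channel(s) not in montage: ",
         paste(ref_channels[is.na(ri)], collapse = ", "), call. = FALSE)
  }
  ref <- apply(x$data[, ri, , drop = FALSE], c(1L, 3L), mean)
  nd <- dim(x$data)
  for (ch in seq_len(nd[2])) x$data[, ch, ] <- x$data[, ch, ] - ref
  x
}

#' Amplitude-threshold artifact rejection
#'
#' Removes every trial containing at least one sample exceeding
#' `threshold` microvolts in absolute value on any analysis channel
#' (default: all non-mastoid channels). Idempotent.
#'
#' @param x An `epoch_set`.
#' @param threshold Rejection threshold in microvolts (default 100).
#' @param channels Channels scanned for violations.
#' @return List with `epochs` (surviving trials) and `log`, a data.frame
#'   with one row per input trial (`trial`, `condition`, `max_abs`,
#'   `channel` of the largest excursion, `rejected`).
#' @export
reject_artifacts <- function(x, threshold = 100,
                             channels = setdiff(x$channels,
                                                mastoid_channels())) {
  stopifnot(inherits(x, "epoch_set"), threshold > 0)
  ci <- match(channels, x$channels)
  if (anyNA(ci)) {
    stop("unknown analysis channel(s): ",
         paste(channels[is.na(ci)], collapse = ", "), call. = FALSE)
  }
  nd <- dim(x$data)
  max_abs <- numeric(nd[1]); worst <- character(nd[1])
  for (tr in seq_len(nd[1])) {
    m <- apply(abs(x$data[tr, ci, , drop = FALSE]), 2L, max)
    j <- which.max(m)
    max_abs[tr] <- m[j]; worst[tr] <- channels[j]
  }
  rejected <- max_abs > threshold
  log <- data.frame(trial = seq_len(nd[1]), condition = x$condition,
                    max_abs = max_abs, channel = worst, rejected = rejected,
                    stringsAsFactors = FALSE)
  keep <- which(!rejected)
  x$data <- x$data[keep, , , drop = FALSE]
  x$condition <- x$condition[keep]
  list(epochs = x, log = log)
}

#' Average epochs into ERP waveforms
#'
#' Pointwise mean over trials, by condition (default) or over all trials.
#'
#' @param x An `epoch_set`.
#' @param by_condition Average within each condition label (default `TRUE`).
#' @return Named list of `erp_waveform` objects (fields `data` =
#'   `channel x sample` matrix, `fs`, `t0`, `channels`, `n_trials`,
#'   `condition`).
#' @export
average_epochs <- function(x, by_condition = TRUE) {
  stopifnot(inherits(x, "epoch_set"))
  if (dim(x$data)[1] == 0L) stop("no trials to average", call. = FALSE)
  groups <- if (by_condition) split(seq_along(x$condition), x$condition)
            else list(all = seq_along(x$condition))
  lapply(groups, function(idx) {
    m <- apply(x$data[idx, , , drop = FALSE], c(2L, 3L), mean)
    rownames(m) <- x$channels
    structure(list(data = m, fs = x$fs, t0 = x$t0, channels = x$channels,
                   n_trials = length(idx),
                   condition = x$condition[idx[1]]),
              class = "erp_waveform")
  })
}

#' Signed peak amplitude in an analysis window
#'
#' For each channel, finds the sample of maximal absolute voltage inside the
#' inclusive `window` (default 250-600 ms, the late-positive-potential
#' range) and reports its signed value and latency. Ties are broken by the
#' earliest latency.
#'
#' @param erp An `erp_waveform` (see [average_epochs()]).
#' @param window Analysis window in ms, endpoints inclusive.
#' @param channels Channels to report (default: all non-mastoid channels of
#'   the waveform). Unknown names are an error.
#' @return data.frame of class `peak_table` with columns `channel`,
#'   `amplitude` (microvolts, sign preserved), `latency_ms`.
#' @export
peak_amplitude <- function(erp, window = c(250, 600),
                           channels = setdiff(erp$channels,
                                              mastoid_channels())) {
  stopifnot(inherits(erp, "erp_waveform"))
  ci <- match(channels, erp$channels)
  if (anyNA(ci)) {
    stop("unknown channel(s): ", paste(channels[is.na(ci)], collapse = ", "),
         call. = FALSE)
  }
  tt <- epoch_times(erp)
  idx <- which(tt >= window[1] & tt <= window[2])
  if (!length(idx)) {
    stop("analysis window [", window[1], ", ", window[2],
         "] ms outside epoch span", call. = FALSE)
  }
  amp <- numeric(length(ci)); lat <- numeric(length(ci))
  for (k in seq_along(ci)) {
    v <- erp$data[ci[k], idx]
    j <- which.max(abs(v))  # first maximum -> earliest latency on ties
    amp[k] <- v[j]; lat[k] <- tt[idx[j]]
  }
  res <- data.frame(channel = channels, amplitude = amp, latency_ms = lat,
                    stringsAsFactors = FALSE)
  attr(res, "window") <- window
  class(res) <- c("peak_table", class(res))
  res
}

#' Frontal-asymmetry valence classification
#'
#' Under the valence hypothesis, relatively greater left-frontal activity
#' accompanies positive affect. The asymmetry index is the mean of the left
#' frontal peaks (Fp1, F3) minus the mean of the right frontal peaks
#' (Fp2, F4); an index above `epsilon` microvolts is classified `like`,
#' below `-epsilon` `dislike`, otherwise `neutral`.
#'
#' @param peaks A `peak_table` (see [peak_amplitude()]) or a named numeric
#'   vector of per-channel amplitudes.
#' @param epsilon Neutrality half-width in microvolts (default 0.5).
#' @param left,right Channel names averaged on each side.
#' @return List of class `asymmetry_result` with `left_mean`, `right_mean`,
#'   `index`, `valence`, `epsilon`.
#' @export
frontal_asymmetry <- function(peaks, epsilon = 0.5,
                              left = c("Fp1", "F3"),
                              right = c("Fp2", "F4")) {
  stopifnot(epsilon >= 0)
  if (inherits(peaks, "peak_table") || is.data.frame(peaks)) {
    amp <- setNames(peaks$amplitude, peaks$channel)
  } else {
    amp <- peaks
  }
  miss <- setdiff(c(left, right), names(amp))
  if (length(miss)) {
    stop("peak table lacks channel(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  left_mean <- mean(amp[left]); right_mean <- mean(amp[right])
  index <- left_mean - right_mean
  valence <- if (index > epsilon) "like"
             else if (index < -epsilon) "dislike" else "neutral"
  structure(list(left_mean = unname(left_mean),
                 right_mean = unname(right_mean),
                 index = unname(index), valence = valence,
                 epsilon = epsilon),
            class = "asymmetry_result")
}

#' @export
print.asymmetry_result <- function(x, ...) {
  cat(sprintf(
    "<asymmetry> left %.3f uV, right %.3f uV, index %+.3f uV (eps %.2f) -> %s\n",
    x$left_mean, x$right_mean, x$index, x$epsilon, x$valence))
  invisible(x)
}

#' Run the full ERP chain
#'
#' Applies the fixed-order pipeline lowpass -> notch -> (segment) ->
#' baseline -> rereference -> reject -> average -> peak -> asymmetry.
#' Accepts either a `continuous_eeg` (with `events`) or an already-segmented
#' `epoch_set`.
#'
#' @param x A `continuous_eeg` or `epoch_set`.
#' @param events,condition Event onsets (samples) and labels; only for
#'   continuous input.
#' @param lowpass_hz,filter_order Low-pass cutoff (Hz) and Butterworth order.
#'   `NULL` cutoff skips the stage.
#' @param notch_hz,notch_q Notch center (Hz; `NULL` skips) and quality.
#' @param seg_window,baseline_window,peak_window Stage windows in ms.
#' @param ref_channels Mastoid reference channels.
#' @param threshold Artifact-rejection threshold in microvolts.
#' @param peak_channels Channels reported in the peak tables.
#' @param epsilon Asymmetry neutrality half-width in microvolts.
#' @return List of class `erp_result` with per-condition `erp` waveforms,
#'   `peaks`, `asymmetry`, and the `rejection` log.
#' @export
run_erp_pipeline <- function(x, events = NULL, condition = NULL,
                             lowpass_hz = 30, filter_order = 4L,
                             notch_hz = 50, notch_q = 30,
                             seg_window = c(-200, 800),
                             baseline_window = c(-200, 0),
                             ref_channels = mastoid_channels(),
                             threshold = 100,
                             peak_window = c(250, 600),
                             peak_channels = NULL,
                             epsilon = 0.5) {
  if (!is.null(lowpass_hz)) x <- lowpass(x, lowpass_hz, filter_order)
  if (!is.null(notch_hz)) x <- notch(x, notch_hz, notch_q)
  if (inherits(x, "continuous_eeg")) {
    if (is.null(events)) {
      stop("continuous input requires event onsets", call. = FALSE)
    }
    x <- segment(x, events, window = seg_window, condition = condition)
  }
  x <- baseline_correct(x, window = baseline_window)
  x <- rereference(x, ref_channels = ref_channels)
  rej <- reject_artifacts(x, threshold = threshold)
  erps <- average_epochs(rej$epochs, by_condition = TRUE)
  if (is.null(peak_channels)) {
    peak_channels <- setdiff(x$channels, ref_channels)
  }
  peaks <- lapply(erps, peak_amplitude, window = peak_window,
                  channels = peak_channels)
  asym <- lapply(peaks, frontal_asymmetry, epsilon = epsilon)
  structure(list(erp = erps, peaks = peaks, asymmetry = asym,
                 rejection = rej$log),
            class = "erp_result")
}
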