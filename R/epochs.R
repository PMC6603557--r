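#' Stimulus-locked epoch container
#'
#' Holds an epochs x channels x samples array with its latency axis, the
#' baseline and stimulus-exclusion windows, per-epoch artifact flags
#' (possibly empty character vectors) and an append-only manual-override
#' log. Constructed by [extract_epochs()].
#'
#' @param data epochs x channels x samples numeric array (microvolts).
#' @param time_ms Latency of each sample relative to the stimulus (ms);
#'   must include 0.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param channel_labels Channel labels (length = dim 2).
#' @param baseline_window_ms Half-open baseline window (default `c(-100, 0)`).
#' @param exclusion_window_ms Closed stimulus-artifact window excluded from
#'   artifact checks (default `c(-2, 2)`).
#' @param bad_channels Channels excluded from artifact checks and averaging.
#' @return An `epoch_set` object.
#' @export
epoch_set <- function(data, time_ms, sample_rate_hz, channel_labels,
                      baseline_window_ms = c(-100, 0),
                      exclusion_window_ms = c(-2, 2),
                      bad_channels = character(0)) {
  stopifnot(length(dim(data)) == 3L, dim(data)[3] == length(time_ms),
            dim(data)[2] == length(channel_labels))
  if (!any(time_ms == 0))
    stop("the time axis must include latency 0", call. = FALSE)
  if (baseline_window_ms[1] >= baseline_window_ms[2] ||
      baseline_window_ms[2] > 0)
    stop("baseline window must precede the stimulus", call. = FALSE)
  structure(list(
    data = data, time_ms = time_ms, sample_rate_hz = sample_rate_hz,
    channel_labels = as.character(channel_labels),
    baseline_window_ms = baseline_window_ms,
    exclusion_window_ms = exclusion_window_ms,
    bad_channels = as.character(bad_channels),
    artifact_flags = replicate(dim(data)[1], character(0), simplify = FALSE),
    auto_flags = NULL,
    manual_overrides = data.frame(epoch = integer(0), action = character(0),
                                  reason = character(0))),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d epochs x %d ch x %d samples @ %g Hz, [%g, %g] ms, %d flagged\n",
              d[1], d[2], d[3], x$sample_rate_hz, min(x$time_ms),
              max(x$time_ms), count_artifacts(x)))
  invisible(x)
}

n_epochs <- function(ep) dim(ep$data)[1]

#' Segment a continuous recording into stimulus-locked epochs
#'
#' Cuts a half-open window `[window_ms[1], window_ms[2])` (in samples:
#' `round(window_ms/1000 * fs)`) around every stimulus event; the sample at
#' latency 0 is the event sample. Events whose window does not fit inside
#' the recording are dropped with a warning.
#'
#' @param rec A `continuous_recording` with events.
#' @param window_ms Epoch window in ms (default `c(-100, 150)`).
#' @return An `epoch_set` (not yet baseline corrected).
#' @export
extract_epochs <- function(rec, window_ms = c(-100, 150)) {
  if (!length(rec$events)) stop("recording has no events", call. = FALSE)
  fs <- rec$sample_rate_hz
  n_pre <- as.integer(round(-window_ms[1] / 1000 * fs))
  n_post <- as.integer(round(window_ms[2] / 1000 * fs))
  rel <- (-n_pre):(n_post - 1L)
  n <- n_samples(rec)
  ok <- rec$events + rel[1] >= 1L & rec$events + rel[length(rel)] <= n
  if (any(!ok))
    warning(sum(!ok), " epoch(s) dropped: window outside the recording",
            call. = FALSE)
  ev <- rec$events[ok]
  if (!length(ev)) stop("no epoch fits inside the recording", call. = FALSE)
  arr <- array(0, c(length(ev), nrow(rec$data), length(rel)))
  for (i in seq_along(ev))
    arr[i, , ] <- rec$data[, ev[i] + rel, drop = FALSE]
  epoch_set(arr, time_ms = rel / fs * 1000, sample_rate_hz = fs,
            channel_labels = rec$channel_labels,
            baseline_window_ms = c(window_ms[1], 0),
            bad_channels = rec$bad_channels)
}

#' Baseline-correct epochs on the pre-stimulus interval
#'
#' Subtracts, per epoch and channel, the mean over the half-open baseline
#' window (default `[-100, 0)` ms). Idempotent.
#'
#' @param ep An `epoch_set`.
#' @return Baseline-corrected `epoch_set`.
#' @export
baseline_correct <- function(ep) {
  sel <- ep$time_ms >= ep$baseline_window_ms[1] &
    ep$time_ms < ep$baseline_window_ms[2]
  if (!any(sel))
    stop("baseline window outside the epoch", call. = FALSE)
  bl <- apply(ep$data[, , sel, drop = FALSE], c(1, 2), mean)
  ep$data <- ep$data - array(bl, dim(ep$data))
  ep
}

#' Keep a subset of epochs
#'
#' @param ep An `epoch_set`.
#' @param keep Logical or integer index over epochs.
#' @return `epoch_set` restricted to `keep` (flags and overrides subset too).
#' @export
subset_epochs <- function(ep, keep) {
  idx <- seq_len(n_epochs(ep))[keep]
  ep$data <- ep$data[idx, , , drop = FALSE]
  ep$artifact_flags <- ep$artifact_flags[idx]
  if (!is.null(ep$auto_flags)) ep$auto_flags <- ep$auto_flags[idx]
  ep$manual_overrides <- ep$manual_overrides[ep$manual_overrides$epoch %in% idx, ]
  ep
}

#' Export per-epoch artifact flags as TSV
#'
#' Columns: `epoch_index`, `rules` (comma-joined rule ids), `manual`.
#' @param ep An `epoch_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_epoch_flags_tsv <- function(ep, path) {
  df <- data.frame(
    epoch_index = seq_len(n_epochs(ep)),
    rules = vapply(ep$artifact_flags, function(f)
      paste(setdiff(f, "manual"), collapse = ","), character(1)),
    manual = vapply(ep$artifact_flags, function(f) "manual" %in% f, logical(1)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
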