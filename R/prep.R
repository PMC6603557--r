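#' Truncate a recording around its stimulus events
#'
#' Keeps the span from `pre_s` seconds before the first event to `post_s`
#' seconds after the last one, clamped to the recording bounds; event
#' indices are re-based so they keep pointing at the same waveform samples.
#'
#' @param rec A `continuous_recording` with at least one event.
#' @param pre_s,post_s Margins in seconds (default 30 each).
#' @return Truncated `continuous_recording`.
#' @export
truncate_recording <- function(rec, pre_s = 30, post_s = 30) {
  if (!length(rec$events)) stop("recording has no events", call. = FALSE)
  fs <- rec$sample_rate_hz
  from <- max(1L, rec$events[1] - as.integer(round(pre_s * fs)))
  to <- min(n_samples(rec), rec$events[length(rec$events)] +
              as.integer(round(post_s * fs)))
  rec$data <- rec$data[, from:to, drop = FALSE]
  rec$events <- rec$events - from + 1L
  rec
}

#' Flag bad channels by robust amplitude deviation
#'
#' Each channel's amplitude is summarized by its robust spread
#' (1.4826 x median absolute deviation, insensitive to sparse transients
#' such as blinks, which must not get a channel flagged); a channel is
#' flagged when the robust z-score of this amplitude across channels
#' (centered on the median, scaled by 1.4826 x MAD) exceeds `z_thresh`, or
#' when its signal is constant (dead channel). Deterministic stand-in for a
#' full standardization pipeline's noisy-channel detection.
#'
#' @param rec A `continuous_recording` with at least 3 channels.
#' @param z_thresh Robust z threshold (default 5).
#' @return Character vector of flagged channel labels.
#' @export
flag_bad_channels <- function(rec, z_thresh = 5) {
  if (nrow(rec$data) < 3L) stop("need at least 3 channels", call. = FALSE)
  amp <- apply(rec$data, 1, stats::mad)
  const <- apply(rec$data, 1, stats::sd) < .Machine$double.eps^0.5
  med <- stats::median(amp)
  mad <- stats::mad(amp)
  z <- if (mad > 0) (amp - med) / mad else rep(0, length(amp))
  rec$channel_labels[const | z > z_thresh]
}

#' Remove power-line noise by sliding-window sinusoidal regression
#'
#' Within consecutive windows of `window_s` seconds, sine/cosine pairs at
#' the line frequency and its harmonics are fit by least squares and
#' subtracted -- but only where a line component actually sticks out:
#' per window, channel and harmonic the fitted amplitude is compared
#' against the mean amplitude fitted at four probe frequencies (2.7 and
#' 5.4 Hz to either side -- pure background by construction), and the fit
#' is subtracted only when its power exceeds `snr_thresh` times the probe
#' level. A recording
#' with no line component therefore passes through unchanged; broadband
#' content away from the line is untouched; no notch filter is involved.
#'
#' @param rec A `continuous_recording`.
#' @param line_hz Line frequency in Hz (default 50).
#' @param n_harmonics Number of harmonics fitted (default 3,
#'   i.e. 50/100/150 Hz).
#' @param window_s Window length in seconds (default 4).
#' @param snr_thresh Power ratio over the probe-frequency background above
#'   which a fitted line component is subtracted (default 30).
#' @return Cleaned `continuous_recording`.
#' @export
remove_line_noise <- function(rec, line_hz = 50, n_harmonics = 3,
                              window_s = 4, snr_thresh = 30) {
  fs <- rec$sample_rate_hz
  freqs <- line_hz * seq_len(n_harmonics)
  if (any(freqs >= fs / 2))
    stop("line harmonic at or above the Nyquist frequency", call. = FALSE)
  n <- n_samples(rec)
  wlen <- as.integer(round(window_s * fs))
  starts <- seq(1L, n, by = wlen)
  pair <- function(f, tt) cbind(sin(2 * pi * f * tt), cos(2 * pi * f * tt))
  for (s in starts) {
    e <- min(n, s + wlen - 1L)
    len <- e - s + 1L
    if (len < 4L * n_harmonics) next
    tt <- (s:e) / fs
    Y <- t(rec$data[, s:e, drop = FALSE])      # samples x channels
    for (f in freqs) {
      amp2 <- function(freq) {                 # squared amplitude of the fit
        X <- pair(freq, tt)
        cf <- solve(crossprod(X), crossprod(X, Y))
        colSums(cf^2)
      }
      X <- pair(f, tt)
      cf <- solve(crossprod(X), crossprod(X, Y))
      line_p <- colSums(cf^2)
      probe_p <- (amp2(f - 5.4) + amp2(f - 2.7) + amp2(f + 2.7) +
                    amp2(f + 5.4)) / 4
      subtract <- line_p > snr_thresh * pmax(probe_p, .Machine$double.eps)
      if (any(subtract))
        Y[, subtract] <- Y[, subtract] - X %*% cf[, subtract, drop = FALSE]
    }
    rec$data[, s:e] <- t(Y)
  }
  rec
}

#' Re-reference to the average of the good channels
#'
#' Subtracts, at every sample, the mean over channels not flagged as bad.
#' Idempotent; afterwards the good-channel mean is zero everywhere. Bad
#' channels are re-referenced too but do not contribute to the mean.
#'
#' @param rec A `continuous_recording`.
#' @return Average-referenced `continuous_recording` (`reference = "average"`).
#' @export
average_reference <- function(rec) {
  good <- !(rec$channel_labels %in% rec$bad_channels)
  if (!any(good)) stop("all channels are flagged bad", call. = FALSE)
  ref <- colMeans(rec$data[good, , drop = FALSE])
  rec$data <- sweep(rec$data, 2, ref)
  rec$reference <- "average"
  rec
}

#' Simplified standardization stage
#'
#' Convenience wrapper running the whole stand-in stage in the conventional
#' order: flag bad channels, remove line noise, average reference.
#'
#' @param rec A `continuous_recording`.
#' @param line_hz Line frequency (default 50 Hz); `NA` skips line removal.
#' @param z_thresh Bad-channel robust z threshold.
#' @return Prepped `continuous_recording` with `bad_channels` populated.
#' @export
run_prep <- function(rec, line_hz = 50, z_thresh = 5) {
  rec$bad_channels <- union(rec$bad_channels, flag_bad_channels(rec, z_thresh))
  if (!is.na(line_hz)) rec <- remove_line_noise(rec, line_hz = line_hz)
  average_reference(rec)
}
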