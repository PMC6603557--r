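#' Average the good epochs
#'
#' Pointwise mean over epochs with an empty artifact flag set; flagged
#' epochs contribute nothing.
#'
#' @param ep An `epoch_set`.
#' @return channels x samples matrix with attributes `n_epochs_averaged`
#'   and `time_ms`.
#' @export
average_good_epochs <- function(ep) {
  keep <- good_epochs(ep)
  if (!any(keep)) stop("no good epochs to average", call. = FALSE)
  avg <- apply(ep$data[keep, , , drop = FALSE], c(2, 3), mean)
  rownames(avg) <- ep$channel_labels
  attr(avg, "n_epochs_averaged") <- sum(keep)
  attr(avg, "time_ms") <- ep$time_ms
  avg
}

#' Measure the N30 amplitude peak-to-peak
#'
#' Finds the most positive sample in the early window (default 15-25 ms)
#' and the most negative sample in the late window (default 25-35 ms); the
#' N30 amplitude is the absolute difference of the two peak amplitudes.
#' Both windows are closed; a peak exactly on the shared 25 ms boundary may
#' be selected by both, and ties break toward the earlier latency. Peaks
#' are extremal samples (no interpolation).
#'
#' @param trace Numeric amplitude vector (microvolts), e.g. the averaged F3
#'   channel.
#' @param time_ms Latency axis matching `trace`.
#' @param pos_window,neg_window Closed search windows in ms.
#' @param channel Channel label recorded in the result (default `"F3"`).
#' @param n_epochs_averaged Bookkeeping: epochs behind the average.
#' @return An `n30_measurement`: positive/negative peak latencies and
#'   amplitudes, `amplitude_uv = |pos - neg|`, `manual_adjusted = FALSE`.
#' @export
measure_n30 <- function(trace, time_ms, pos_window = c(15, 25),
                        neg_window = c(25, 35), channel = "F3",
                        n_epochs_averaged = NA_integer_) {
  stopifnot(length(trace) == length(time_ms))
  ip <- which(time_ms >= pos_window[1] & time_ms <= pos_window[2])
  im <- which(time_ms >= neg_window[1] & time_ms <= neg_window[2])
  if (!length(ip) || !length(im))
    stop("peak window outside the trace's time span", call. = FALSE)
  wp <- ip[which.max(trace[ip])]   # which.max: first (earliest) maximum
  wn <- im[which.min(trace[im])]
  structure(list(channel = channel,
                 pos_peak = c(latency_ms = time_ms[wp], amplitude_uv = trace[wp]),
                 neg_peak = c(latency_ms = time_ms[wn], amplitude_uv = trace[wn]),
                 amplitude_uv = abs(trace[wp] - trace[wn]),
                 manual_adjusted = FALSE,
                 n_epochs_averaged = n_epochs_averaged,
                 pos_window = pos_window, neg_window = neg_window,
                 trace = trace, time_ms = time_ms),
            class = "n30_measurement")
}

#' @export
print.n30_measurement <- function(x, ...) {
  cat(sprintf("<n30_measurement> %s: P %.2f uV @ %.1f ms, N %.2f uV @ %.1f ms, amplitude %.2f uV%s\n",
              x$channel, x$pos_peak["amplitude_uv"], x$pos_peak["latency_ms"],
              x$neg_peak["amplitude_uv"], x$neg_peak["latency_ms"],
              x$amplitude_uv, if (x$manual_adjusted) " (manually adjusted)" else ""))
  invisible(x)
}

#' Manually override the identified peak latencies
#'
#' Re-reads the peak amplitudes at the supplied latencies (nearest sample)
#' and recomputes the amplitude; used when the automatic pick latched onto
#' the wrong local extremum. Latencies must stay inside their windows.
#'
#' @param m An `n30_measurement`.
#' @param pos_latency_ms,neg_latency_ms Optional replacement latencies (ms).
#' @return Updated `n30_measurement` with `manual_adjusted = TRUE` if
#'   anything changed.
#' @export
override_peaks <- function(m, pos_latency_ms = NULL, neg_latency_ms = NULL) {
  if (is.null(pos_latency_ms) && is.null(neg_latency_ms)) return(m)
  reread <- function(lat, window, what) {
    if (lat < window[1] || lat > window[2])
      stop(what, " override latency outside its window", call. = FALSE)
    i <- which.min(abs(m$time_ms - lat))
    c(latency_ms = m$time_ms[i], amplitude_uv = m$trace[i])
  }
  if (!is.null(pos_latency_ms))
    m$pos_peak <- reread(pos_latency_ms, m$pos_window, "positive-peak")
  if (!is.null(neg_latency_ms))
    m$neg_peak <- reread(neg_latency_ms, m$neg_window, "negative-peak")
  m$amplitude_uv <- abs(m$pos_peak[["amplitude_uv"]] - m$neg_peak[["amplitude_uv"]])
  m$manual_adjusted <- TRUE
  m
}

#' N30 measurement straight from an epoch set
#'
#' Averages the good epochs and measures N30 on the requested channel.
#'
#' @param ep An `epoch_set`.
#' @param channel Channel label (default `"F3"`).
#' @param ... Passed to [measure_n30()].
#' @return An `n30_measurement`.
#' @export
n30_from_epochs <- function(ep, channel = "F3", ...) {
  avg <- average_good_epochs(ep)
  if (!channel %in% rownames(avg))
    stop("channel ", channel, " not present", call. = FALSE)
  measure_n30(avg[channel, ], attr(avg, "time_ms"), channel = channel,
              n_epochs_averaged = attr(avg, "n_epochs_averaged"), ...)
}
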