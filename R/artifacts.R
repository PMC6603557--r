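#' Artifact rule thresholds
#'
#' The five epoch-level rules with their defaults: (abs) absolute voltage
#' above 100 uV; (p2p) peak-to-peak above 150 uV in 200 ms windows stepped
#' by 100 ms; (step) half-window mean difference above 100 uV in 200 ms
#' windows stepped by 50 ms; (s2s) sample-to-sample difference above 50 uV;
#' (flat) absolute voltage below 2 uV for more than 125 ms. Samples inside
#' the stimulus-exclusion window are masked out of every check.
#'
#' @param abs_thresh_uv,p2p_thresh_uv,step_thresh_uv,s2s_thresh_uv,flat_thresh_uv
#'   Rule thresholds in microvolts.
#' @param p2p_window_ms,p2p_step_ms,step_window_ms,step_step_ms Sliding-window
#'   geometry in ms.
#' @param flat_min_dur_ms Minimum flatline run duration in ms (strict).
#' @return An `artifact_rules` object.
#' @export
artifact_rules <- function(abs_thresh_uv = 100,
                           p2p_thresh_uv = 150, p2p_window_ms = 200,
                           p2p_step_ms = 100,
                           step_thresh_uv = 100, step_window_ms = 200,
                           step_step_ms = 50,
                           s2s_thresh_uv = 50,
                           flat_thresh_uv = 2, flat_min_dur_ms = 125) {
  vals <- c(abs_thresh_uv, p2p_thresh_uv, p2p_window_ms, p2p_step_ms,
            step_thresh_uv, step_window_ms, step_step_ms, s2s_thresh_uv,
            flat_thresh_uv, flat_min_dur_ms)
  if (any(vals <= 0)) stop("all rule parameters must be positive", call. = FALSE)
  structure(list(abs_thresh_uv = abs_thresh_uv,
                 p2p_thresh_uv = p2p_thresh_uv, p2p_window_ms = p2p_window_ms,
                 p2p_step_ms = p2p_step_ms,
                 step_thresh_uv = step_thresh_uv,
                 step_window_ms = step_window_ms, step_step_ms = step_step_ms,
                 s2s_thresh_uv = s2s_thresh_uv,
                 flat_thresh_uv = flat_thresh_uv,
                 flat_min_dur_ms = flat_min_dur_ms),
            class = "artifact_rules")
}

# Window start indices: anchored at sample 1, advancing by `step`, plus one
# final window flush with the trace end so the tail is always covered.
window_starts <- function(n, win, step) {
  if (win > n) stop("rule window longer than the epoch", call. = FALSE)
  s <- seq(1L, n - win + 1L, by = step)
  if (s[length(s)] != n - win + 1L) s <- c(s, n - win + 1L)
  s
}

#' Maximum sliding-window peak-to-peak voltage
#'
#' Maximum over window placements of `max - min` of the unmasked samples in
#' the window. Windows with fewer than two unmasked samples are skipped.
#'
#' @param trace Numeric vector (microvolts).
#' @param window_ms,step_ms Window geometry in ms.
#' @param fs Sampling rate in Hz.
#' @param mask Logical vector, `TRUE` = excluded sample (default none).
#' @return Maximum peak-to-peak voltage in microvolts.
#' @export
sliding_p2p <- function(trace, window_ms, step_ms, fs, mask = NULL) {
  n <- length(trace)
  if (is.null(mask)) mask <- rep(FALSE, n)
  if (all(mask)) stop("trace fully masked", call. = FALSE)
  win <- max(2L, as.integer(round(window_ms / 1000 * fs)))
  step <- max(1L, as.integer(round(step_ms / 1000 * fs)))
  best <- -Inf
  for (s in window_starts(n, win, step)) {
    idx <- s:(s + win - 1L)
    v <- trace[idx][!mask[idx]]
    if (length(v) >= 2L) best <- max(best, max(v) - min(v))
  }
  if (!is.finite(best)) stop("no window has two unmasked samples", call. = FALSE)
  best
}

#' Maximum sliding-window step statistic
#'
#' Per window, the absolute difference between the mean of the unmasked
#' samples in the second half and in the first half; the maximum over the
#' window grid is returned. Windows with an empty half are skipped.
#'
#' @inheritParams sliding_p2p
#' @return Maximum half-window mean difference in microvolts.
#' @export
step_statistic <- function(trace, window_ms, step_ms, fs, mask = NULL) {
  n <- length(trace)
  if (is.null(mask)) mask <- rep(FALSE, n)
  if (all(mask)) stop("trace fully masked", call. = FALSE)
  win <- max(2L, as.integer(round(window_ms / 1000 * fs)))
  step <- max(1L, as.integer(round(step_ms / 1000 * fs)))
  half <- win %/% 2L
  best <- -Inf
  for (s in window_starts(n, win, step)) {
    i1 <- s:(s + half - 1L)
    i2 <- (s + half):(s + win - 1L)
    v1 <- trace[i1][!mask[i1]]
    v2 <- trace[i2][!mask[i2]]
    if (length(v1) && length(v2)) best <- max(best, abs(mean(v2) - mean(v1)))
  }
  if (!is.finite(best)) stop("no window has both halves unmasked", call. = FALSE)
  best
}

# Longest run (ms) of consecutive unmasked samples with |v| < thresh;
# masked samples break a run.
flat_run_ms <- function(trace, thresh, fs, mask) {
  quiet <- (abs(trace) < thresh) & !mask
  r <- rle(quiet)
  len <- r$lengths[r$values]
  if (!length(len)) return(0)
  max(len) / fs * 1000
}

# Max |difference| between adjacent-in-time samples that are both unmasked.
s2s_max <- function(trace, mask) {
  ok <- !mask[-length(mask)] & !mask[-1]
  if (!any(ok)) return(0)
  max(abs(diff(trace))[ok])
}

#' Detect artifact epochs with the five-rule battery
#'
#' Marks (never deletes) each epoch with the identifiers of the rules
#' violated on any tested channel: `"abs"`, `"p2p"`, `"step"`, `"s2s"`,
#' `"flat"`. Samples inside the stimulus-exclusion window (default
#' -2 to 2 ms, inclusive) are excluded from every check; sliding windows
#' straddling the mask evaluate only their unmasked samples. The automatic
#' flags are also stored as provenance (`auto_flags`), untouched by later
#' manual overrides.
#'
#' @param ep An `epoch_set`.
#' @param rules An [artifact_rules()] object.
#' @param channels Channels to test; default all channels not flagged bad.
#' @return The `epoch_set` with `artifact_flags`/`auto_flags` populated.
#' @export
detect_artifacts <- function(ep, rules = artifact_rules(), channels = NULL) {
  if (is.null(channels)) channels <- setdiff(ep$channel_labels, ep$bad_channels)
  if (!length(channels)) stop("no channels to test", call. = FALSE)
  ci <- match(channels, ep$channel_labels)
  if (anyNA(ci)) stop("unknown channel in `channels`", call. = FALSE)
  fs <- ep$sample_rate_hz
  mask <- ep$time_ms >= ep$exclusion_window_ms[1] &
    ep$time_ms <= ep$exclusion_window_ms[2]
  flags <- vector("list", n_epochs(ep))
  for (e in seq_len(n_epochs(ep))) {
    mat <- matrix(ep$data[e, ci, ], nrow = length(ci))
    hit <- character(0)
    for (ch in seq_len(nrow(mat))) {
      tr <- mat[ch, ]
      if (!("abs" %in% hit) && any(abs(tr[!mask]) > rules$abs_thresh_uv))
        hit <- c(hit, "abs")
      if (!("p2p" %in% hit) &&
          sliding_p2p(tr, rules$p2p_window_ms, rules$p2p_step_ms, fs,
                      mask) > rules$p2p_thresh_uv)
        hit <- c(hit, "p2p")
      if (!("step" %in% hit) &&
          step_statistic(tr, rules$step_window_ms, rules$step_step_ms, fs,
                         mask) > rules$step_thresh_uv)
        hit <- c(hit, "step")
      if (!("s2s" %in% hit) && s2s_max(tr, mask) > rules$s2s_thresh_uv)
        hit <- c(hit, "s2s")
      if (!("flat" %in% hit) &&
          flat_run_ms(tr, rules$flat_thresh_uv, fs, mask) > rules$flat_min_dur_ms)
        hit <- c(hit, "flat")
      if (length(hit) == 5L) break
    }
    flags[[e]] <- sort(hit)
  }
  ep$artifact_flags <- flags
  ep$auto_flags <- flags
  ep
}

#' Apply manual overrides to the automatic artifact flags
#'
#' Mirrors the manual verification pass: an `"unmark"` clears an epoch's
#' flags (e.g. frontal step-like epochs that are eye blinks and should be
#' kept), a `"mark"` adds the `"manual"` flag. Every action is appended to
#' the override log; the original automatic flags stay in `auto_flags`.
#'
#' @param ep An `epoch_set` (after [detect_artifacts()]).
#' @param overrides `data.frame` with columns `epoch` (index), `action`
#'   (`"mark"` or `"unmark"`) and `reason`.
#' @return Updated `epoch_set`.
#' @export
apply_manual_overrides <- function(ep, overrides) {
  if (!nrow(overrides)) return(ep)
  stopifnot(all(c("epoch", "action") %in% names(overrides)))
  if (is.null(overrides$reason)) overrides$reason <- ""
  if (any(overrides$epoch < 1L | overrides$epoch > n_epochs(ep)))
    stop("override refers to an unknown epoch index", call. = FALSE)
  if (!all(overrides$action %in% c("mark", "unmark")))
    stop("override action must be 'mark' or 'unmark'", call. = FALSE)
  for (i in seq_len(nrow(overrides))) {
    e <- overrides$epoch[i]
    if (overrides$action[i] == "unmark") {
      ep$artifact_flags[[e]] <- character(0)
    } else {
      ep$artifact_flags[[e]] <- union(ep$artifact_flags[[e]], "manual")
    }
  }
  ep$manual_overrides <- rbind(ep$manual_overrides,
                               overrides[, c("epoch", "action", "reason")])
  ep
}

#' Number of epochs currently marked as artifacts
#'
#' @param ep An `epoch_set`.
#' @return Integer count of epochs with a non-empty flag set.
#' @export
count_artifacts <- function(ep) sum(lengths(ep$artifact_flags) > 0L)

good_epochs <- function(ep) lengths(ep$artifact_flags) == 0L
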