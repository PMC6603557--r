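#' Continuous multi-channel EEG recording
#'
#' Container for a channels x samples voltage matrix (in microvolts) with a
#' sampling rate, 10-20 channel labels, stimulus events (1-based sample
#' indices), a set of flagged bad channels, and the current reference.
#'
#' @param data Numeric channels x samples matrix (microvolts).
#' @param sample_rate_hz Sampling rate in Hz.
#' @param channel_labels Character vector, one label per row of `data`.
#' @param events Integer vector of strictly increasing stimulus sample
#'   indices within the data range.
#' @param bad_channels Character subset of `channel_labels`.
#' @param reference `"raw"` or `"average"`.
#' @return A `continuous_recording` object.
#' @export
continuous_recording <- function(data, sample_rate_hz, channel_labels,
                                 events = integer(0),
                                 bad_channels = character(0),
                                 reference = c("raw", "average")) {
  reference <- match.arg(reference)
  data <- as.matrix(data)
  if (!is.numeric(data) || anyNA(data) || any(!is.finite(data)))
    stop("`data` must be a finite numeric matrix", call. = FALSE)
  if (length(channel_labels) != nrow(data))
    stop("one channel label per data row is required", call. = FALSE)
  events <- as.integer(events)
  if (length(events)) {
    if (is.unsorted(events, strictly = TRUE))
      stop("`events` must be strictly increasing", call. = FALSE)
    if (min(events) < 1L || max(events) > ncol(data))
      stop("`events` must lie within the data range", call. = FALSE)
  }
  if (!all(bad_channels %in% channel_labels))
    stop("`bad_channels` must be a subset of `channel_labels`", call. = FALSE)
  rownames(data) <- channel_labels
  structure(list(data = data, sample_rate_hz = sample_rate_hz,
                 channel_labels = as.character(channel_labels),
                 events = events, bad_channels = as.character(bad_channels),
                 reference = reference),
            class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf(paste0("<continuous_recording> %d ch x %d samples @ %g Hz ",
                     "(%.1f s), %d events, %d bad ch, reference: %s\n"),
              nrow(x$data), ncol(x$data), x$sample_rate_hz,
              ncol(x$data) / x$sample_rate_hz, length(x$events),
              length(x$bad_channels), x$reference))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)

#' Write / read a recording in the delimited-matrix dialect
#'
#' The signal matrix is written as TSV with one column per channel (header =
#' channel labels) and one row per sample; events go to a two-column TSV
#' (`sample_index`, `code`); sampling rate, bad channels and reference to a
#' small JSON sidecar.
#'
#' @param rec A `continuous_recording`.
#' @param path Path of the signal TSV; the events file gets suffix
#'   `_events.tsv`, the sidecar `.json`.
#' @return `write_recording_tsv`: invisibly, `path`.
#'   `read_recording_tsv`: the reconstructed `continuous_recording`.
#' @export
write_recording_tsv <- function(rec, path) {
  m <- t(rec$data)
  colnames(m) <- rec$channel_labels
  utils::write.table(m, path, sep = "\t", row.names = FALSE, quote = FALSE)
  ev <- data.frame(sample_index = rec$events,
                   code = rep("stim", length(rec$events)))
  utils::write.table(ev, events_path(path), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(sample_rate_hz = rec$sample_rate_hz,
                            bad_channels = rec$bad_channels,
                            reference = rec$reference),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording_tsv
#' @export
read_recording_tsv <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   check.names = FALSE))
  ev <- utils::read.table(events_path(path), header = TRUE, sep = "\t")
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  bad <- meta$bad_channels
  if (is.null(bad) || !length(bad)) bad <- character(0)
  continuous_recording(t(m), meta$sample_rate_hz, colnames(m),
                       events = ev$sample_index, bad_channels = bad,
                       reference = meta$reference)
}

events_path <- function(path) sub("(\\.[^.]+)?$", "_events.tsv", path, perl = TRUE)
sidecar_path <- function(path) sub("(\\.[^.]+)?$", ".json", path, perl = TRUE)
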