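#' ICA model: unmixing/mixing matrices with component labels
#'
#' The decomposition algorithm itself is a pluggable contract: any
#' components x channels unmixing matrix (with per-component labels) can be
#' supplied, e.g. a ground-truth unmixing from the synthetic generator or
#' an externally computed decomposition read from delimited text.
#'
#' @param unmixing components x channels numeric matrix.
#' @param labels Per-component label: `"brain"`, `"muscle"`, `"eye"`,
#'   `"channel_noise"` or `"line_noise"`.
#' @param channel_subset Labels of the channels the model was fit on
#'   (columns of `unmixing`).
#' @param mixing Optional channels x components mixing matrix; the
#'   Moore-Penrose pseudo-inverse of `unmixing` when omitted.
#' @return An `ica_model` object.
#' @export
ica_model <- function(unmixing, labels, channel_subset, mixing = NULL) {
  unmixing <- as.matrix(unmixing)
  known <- c("brain", "muscle", "eye", "channel_noise", "line_noise")
  if (!all(labels %in% known))
    stop("labels must be one of: ", paste(known, collapse = ", "), call. = FALSE)
  if (length(labels) != nrow(unmixing))
    stop("one label per component is required", call. = FALSE)
  if (length(channel_subset) != ncol(unmixing))
    stop("one channel label per unmixing column is required", call. = FALSE)
  if (is.null(mixing)) mixing <- pracma::pinv(unmixing)
  structure(list(unmixing = unmixing, mixing = as.matrix(mixing),
                 labels = as.character(labels),
                 channel_subset = as.character(channel_subset)),
            class = "ica_model")
}

#' @export
print.ica_model <- function(x, ...) {
  cat(sprintf("<ica_model> %d components on %d channels (%s)\n",
              nrow(x$unmixing), ncol(x$unmixing),
              paste(sprintf("%s:%d", names(table(x$labels)), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' Read / write an ICA model as delimited text
#'
#' The unmixing matrix is stored as TSV with a channel-label header row and
#' one component per line; labels go to a one-label-per-line file.
#'
#' @param model An `ica_model`.
#' @param path Unmixing TSV path; labels file gets suffix `_labels.txt`.
#' @return `read_ica_model` returns the `ica_model`.
#' @export
write_ica_model <- function(model, path) {
  m <- model$unmixing
  colnames(m) <- model$channel_subset
  utils::write.table(m, path, sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(model$labels, sub("(\\.[^.]+)?$", "_labels.txt", path, perl = TRUE))
  invisible(path)
}

#' @rdname write_ica_model
#' @export
read_ica_model <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   check.names = FALSE))
  labels <- readLines(sub("(\\.[^.]+)?$", "_labels.txt", path, perl = TRUE))
  ica_model(m, labels = labels, channel_subset = colnames(m))
}

#' Prepare a recording for ICA decomposition
#'
#' Applies the conventional pre-decomposition reductions: FIR anti-alias
#' lowpass (cutoff 0.8 x target Nyquist) followed by integer-factor
#' decimation, epoching, rejection of flagged epochs, and removal of bad
#' channels.
#'
#' @param rec A `continuous_recording` (typically 1 Hz high-pass filtered).
#' @param epoch_flags Optional list of per-epoch flag sets (from
#'   [detect_artifacts()] on the matching epoching); flagged epochs are
#'   rejected.
#' @param target_rate_hz Target sampling rate; must divide the recording
#'   rate (default 512).
#' @param window_ms Epoch window (default `c(-100, 150)` ms).
#' @return An `epoch_set` at the target rate, bad channels removed.
#' @export
prepare_for_ica <- function(rec, epoch_flags = NULL, target_rate_hz = 512,
                            window_ms = c(-100, 150)) {
  fs <- rec$sample_rate_hz
  fac <- fs / target_rate_hz
  if (abs(fac - round(fac)) > 1e-9)
    stop("target rate must divide the sampling rate", call. = FALSE)
  fac <- as.integer(round(fac))
  if (fac > 1L) {
    aa <- design_fir(filter_spec("fir_kaiser", "lowpass",
                                 cutoffs_hz = 0.8 * target_rate_hz / 2,
                                 sample_rate_hz = fs, transition_bw_hz = 20))
    rec <- apply_zero_phase(aa, rec)
    keep <- seq(1L, n_samples(rec), by = fac)
    rec$data <- rec$data[, keep, drop = FALSE]
    rec$events <- as.integer((rec$events - 1L) %/% fac + 1L)
    rec$sample_rate_hz <- target_rate_hz
  }
  ep <- extract_epochs(rec, window_ms = window_ms)
  if (!is.null(epoch_flags)) {
    if (length(epoch_flags) != n_epochs(ep))
      stop("`epoch_flags` length does not match the epoch count", call. = FALSE)
    ep$artifact_flags <- epoch_flags
    ep <- subset_epochs(ep, good_epochs(ep))
    ep$artifact_flags <- replicate(n_epochs(ep), character(0), simplify = FALSE)
  }
  good <- setdiff(ep$channel_labels, ep$bad_channels)
  ci <- match(good, ep$channel_labels)
  ep$data <- ep$data[, ci, , drop = FALSE]
  ep$channel_labels <- good
  ep$bad_channels <- character(0)
  ep
}

#' Component activations from an unmixing matrix
#'
#' `activations = unmixing %*% data` restricted to the model's channel
#' subset, per epoch.
#'
#' @param ep An `epoch_set` whose channels include `model$channel_subset`.
#' @param model An `ica_model`.
#' @return epochs x components x samples array.
#' @export
apply_ica_weights <- function(ep, model) {
  ci <- match(model$channel_subset, ep$channel_labels)
  if (anyNA(ci))
    stop("epoch channels do not cover the model's channel subset", call. = FALSE)
  d <- dim(ep$data)
  out <- array(0, c(d[1], nrow(model$unmixing), d[3]))
  for (e in seq_len(d[1]))
    out[e, , ] <- model$unmixing %*% matrix(ep$data[e, ci, ], nrow = length(ci))
  out
}

#' Remove labelled components by back-projection
#'
#' Reconstructs the modeled channels from the retained components only:
#' `cleaned = mixing[, retained] %*% activations[retained, ]`. Channels
#' outside the model's subset are left untouched. Removing nothing is the
#' identity on the modeled subspace.
#'
#' @param ep An `epoch_set`.
#' @param model An `ica_model`.
#' @param remove_labels Labels to remove (default all non-brain categories).
#' @return Cleaned `epoch_set`.
#' @export
remove_components <- function(ep, model,
                              remove_labels = c("muscle", "eye",
                                                "channel_noise", "line_noise")) {
  keep <- !(model$labels %in% remove_labels)
  if (!any(keep)) stop("all components would be removed", call. = FALSE)
  ci <- match(model$channel_subset, ep$channel_labels)
  if (anyNA(ci))
    stop("epoch channels do not cover the model's channel subset", call. = FALSE)
  proj <- model$mixing[, keep, drop = FALSE] %*%
    model$unmixing[keep, , drop = FALSE]
  for (e in seq_len(n_epochs(ep)))
    ep$data[e, ci, ] <- proj %*% matrix(ep$data[e, ci, ],
                                        nrow = length(ci))
  ep
}

# Fold a spatial re-referencing operator into a ground-truth ICA model so it
# stays valid for data that were average referenced after mixing: the
# effective mixing is R %*% mixing (R = average-reference projector over the
# modeled channels) and the unmixing is its pseudo-inverse.
rereference_ica_model <- function(model) {
  m <- length(model$channel_subset)
  R <- diag(m) - matrix(1 / m, m, m)
  mix <- R %*% model$mixing
  ica_model(pracma::pinv(mix), labels = model$labels,
            channel_subset = model$channel_subset, mixing = mix)
}
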