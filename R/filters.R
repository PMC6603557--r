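#' Kaiser window shape parameter from the ripple specification
#'
#' Maps a peak approximation-error (ripple) specification to the Kaiser window
#' shape parameter \eqn{\beta} via the standard attenuation formula: with
#' \eqn{A = -20\log_{10}(\delta)} dB,
#' \deqn{\beta = 0.1102(A - 8.7) \quad (A > 50)}
#' \deqn{\beta = 0.5842(A - 21)^{0.4} + 0.07886(A - 21) \quad (21 \le A \le 50)}
#' and \eqn{\beta = 0} below 21 dB (rectangular-window regime).
#'
#' @param ripple Peak ripple \eqn{\delta}, strictly between 0 and 1. The
#'   default 0.001 corresponds to 60 dB stopband attenuation and
#'   \eqn{\beta = 5.653}.
#' @return Non-negative numeric scalar \eqn{\beta}.
#' @examples
#' kaiser_beta_from_ripple(0.001) # 5.653
#' @export
kaiser_beta_from_ripple <- function(ripple = 0.001) {
  stopifnot(is.numeric(ripple), length(ripple) == 1L, is.finite(ripple))
  if (ripple <= 0 || ripple >= 1)
    stop("`ripple` must lie strictly inside (0, 1)", call. = FALSE)
  A <- -20 * log10(ripple)
  if (A > 50) {
    0.1102 * (A - 8.7)
  } else if (A >= 21) {
    0.5842 * (A - 21)^0.4 + 0.07886 * (A - 21)
  } else {
    0
  }
}

#' FIR order for a requested transition bandwidth
#'
#' Kaiser's empirical design relation: the number of taps needed for a
#' windowed-sinc filter to move from passband to stopband over
#' `transition_bw_hz` at attenuation \eqn{A = -20\log_{10}(\delta)} is
#' \deqn{N \approx \frac{A - 7.95}{2.285\,\Delta\omega}, \qquad
#'       \Delta\omega = 2\pi\,\Delta f / f_s,}
#' rounded up to the next even integer so the group delay is an integer
#' number of samples. Order and transition bandwidth are inversely
#' proportional.
#'
#' @param transition_bw_hz Transition bandwidth in Hz (> 0, < Nyquist).
#' @param sample_rate_hz Sampling rate in Hz.
#' @param ripple Peak ripple, as in [kaiser_beta_from_ripple()].
#' @return Even integer filter order.
#' @examples
#' fir_order_from_transition(1, 2048)   # ~7420
#' fir_order_from_transition(1.5, 2048) # ~4948
#' @export
fir_order_from_transition <- function(transition_bw_hz, sample_rate_hz,
                                      ripple = 0.001) {
  stopifnot(is.numeric(transition_bw_hz), is.numeric(sample_rate_hz))
  if (transition_bw_hz <= 0)
    stop("`transition_bw_hz` must be positive", call. = FALSE)
  if (sample_rate_hz <= 0)
    stop("`sample_rate_hz` must be positive", call. = FALSE)
  if (transition_bw_hz >= sample_rate_hz / 2)
    stop("`transition_bw_hz` must be below the Nyquist frequency", call. = FALSE)
  A <- -20 * log10(ripple)
  dw <- 2 * pi * transition_bw_hz / sample_rate_hz
  n <- (A - 7.95) / (2.285 * dw)
  as.integer(2 * ceiling(n / 2))
}

#' Declarative filter specification
#'
#' @param filter_class `"fir_kaiser"` or `"iir_butterworth"`.
#' @param mode `"highpass"`, `"lowpass"` or `"bandpass"`.
#' @param cutoffs_hz One cutoff (high/lowpass) or two strictly increasing
#'   cutoffs (bandpass), all below Nyquist.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param fir_order Even FIR order; derived from `transition_bw_hz` when
#'   omitted (FIR only).
#' @param transition_bw_hz Requested transition width in Hz; derived from
#'   `fir_order` when omitted (FIR only).
#' @param ripple Peak ripple used for the Kaiser \eqn{\beta} and order
#'   derivations.
#' @param kaiser_beta Kaiser shape parameter; default derived from `ripple`.
#' @param iir_order_per_edge Butterworth order per band edge (default 2).
#' @param zero_phase Logical; zero-phase application semantics.
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(filter_class = c("fir_kaiser", "iir_butterworth"),
                        mode = c("bandpass", "highpass", "lowpass"),
                        cutoffs_hz,
                        sample_rate_hz,
                        fir_order = NULL,
                        transition_bw_hz = NULL,
                        ripple = 0.001,
                        kaiser_beta = kaiser_beta_from_ripple(ripple),
                        iir_order_per_edge = 2L,
                        zero_phase = TRUE) {
  filter_class <- match.arg(filter_class)
  mode <- match.arg(mode)
  cutoffs_hz <- as.numeric(cutoffs_hz)
  nyq <- sample_rate_hz / 2
  if (mode == "bandpass" && length(cutoffs_hz) != 2L)
    stop("bandpass requires two cutoffs", call. = FALSE)
  if (mode != "bandpass" && length(cutoffs_hz) != 1L)
    stop(mode, " requires exactly one cutoff", call. = FALSE)
  if (any(cutoffs_hz <= 0) || any(cutoffs_hz >= nyq))
    stop("cutoffs must lie strictly inside (0, Nyquist)", call. = FALSE)
  if (length(cutoffs_hz) == 2L && diff(cutoffs_hz) <= 0)
    stop("cutoffs must be strictly increasing", call. = FALSE)
  if (filter_class == "fir_kaiser") {
    if (is.null(fir_order) && is.null(transition_bw_hz))
      stop("FIR design needs `fir_order` or `transition_bw_hz`", call. = FALSE)
    if (is.null(fir_order))
      fir_order <- fir_order_from_transition(transition_bw_hz, sample_rate_hz, ripple)
    fir_order <- as.integer(fir_order)
    if (fir_order <= 0L || fir_order %% 2L != 0L)
      stop("`fir_order` must be a positive even integer", call. = FALSE)
    if (is.null(transition_bw_hz)) {
      A <- -20 * log10(ripple)
      transition_bw_hz <- (A - 7.95) * sample_rate_hz / (2.285 * 2 * pi * fir_order)
    }
  }
  structure(list(
    filter_class = filter_class, mode = mode, cutoffs_hz = cutoffs_hz,
    sample_rate_hz = sample_rate_hz, fir_order = fir_order,
    transition_bw_hz = transition_bw_hz, ripple = ripple,
    kaiser_beta = kaiser_beta, iir_order_per_edge = as.integer(iir_order_per_edge),
    zero_phase = isTRUE(zero_phase)), class = "filter_spec")
}

# Kaiser window of length n_taps (order + 1), symmetric.
kaiser_window <- function(n_taps, beta) {
  m <- n_taps - 1
  k <- 0:m
  x <- beta * sqrt(pmax(0, 1 - (2 * k / m - 1)^2))
  besselI(x, 0) / besselI(beta, 0)
}

# Kaiser-windowed ideal-sinc lowpass kernel, -6 dB at the cutoff,
# unit DC gain (tap sum normalized to 1).
fir_lowpass_taps <- function(cutoff_hz, order, beta, fs) {
  m <- order / 2
  k <- (-m):m
  fc <- cutoff_hz / fs
  h <- 2 * fc * ifelse(k == 0, 1, sin(2 * pi * fc * k) / (2 * pi * fc * k))
  h <- h * kaiser_window(order + 1, beta)
  h / sum(h)
}

# Highpass by spectral inversion of the complementary lowpass.
fir_highpass_taps <- function(cutoff_hz, order, beta, fs) {
  h <- -fir_lowpass_taps(cutoff_hz, order, beta, fs)
  h[order / 2 + 1] <- h[order / 2 + 1] + 1
  h
}

#' Design a Kaiser windowed-sinc FIR filter
#'
#' Builds a linear-phase windowed-sinc kernel with magnitude 0.5 (-6 dB) at
#' each cutoff. Highpass designs use spectral inversion of the complementary
#' lowpass; bandpass designs are realized as a highpass--lowpass cascade with
#' the stated order used for each stage, so the transition semantics hold per
#' edge. The realized transition width of each stage is measured from the
#' frequency response (see [measure_transition_bw()]).
#'
#' @param spec A [filter_spec()] with `filter_class = "fir_kaiser"`.
#' @return A `designed_filter` object with one `fir` stage per band edge.
#' @export
design_fir <- function(spec) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$filter_class != "fir_kaiser")
    stop("spec is not a Kaiser FIR specification", call. = FALSE)
  order <- spec$fir_order
  if (order %% 2L != 0L) stop("FIR order must be even", call. = FALSE)
  fs <- spec$sample_rate_hz
  nyq <- fs / 2
  tbw <- spec$transition_bw_hz
  for (fc in spec$cutoffs_hz) {
    if (fc + tbw / 2 >= nyq && fc > nyq - 1e-9)
      stop("cutoff too close to Nyquist for the requested transition", call. = FALSE)
  }
  beta <- spec$kaiser_beta
  stages <- switch(spec$mode,
    lowpass = list(fir_stage(fir_lowpass_taps(spec$cutoffs_hz, order, beta, fs),
                             spec$cutoffs_hz, "lowpass")),
    highpass = list(fir_stage(fir_highpass_taps(spec$cutoffs_hz, order, beta, fs),
                              spec$cutoffs_hz, "highpass")),
    bandpass = list(
      fir_stage(fir_highpass_taps(spec$cutoffs_hz[1], order, beta, fs),
                spec$cutoffs_hz[1], "highpass"),
      fir_stage(fir_lowpass_taps(spec$cutoffs_hz[2], order, beta, fs),
                spec$cutoffs_hz[2], "lowpass")))
  filt <- structure(list(spec = spec, stages = stages), class = "designed_filter")
  filt$measured_transition_bw_hz <-
    vapply(seq_along(stages), function(i) measure_transition_bw(filt, stage = i),
           numeric(1))
  filt
}

fir_stage <- function(taps, cutoff_hz, edge) {
  list(type = "fir", taps = taps, cutoff_hz = cutoff_hz, edge = edge)
}

#' Design a Butterworth IIR filter
#'
#' Bilinear-transform Butterworth design (via [signal::butter()]) of the
#' stated order per band edge; a bandpass is realized as a highpass stage
#' cascaded with a lowpass stage so that each edge has its own maximally flat
#' (monotone) response with \eqn{|H| = 2^{-1/2}} at its cutoff per single pass.
#'
#' @param spec A [filter_spec()] with `filter_class = "iir_butterworth"`.
#' @return A `designed_filter` object with one `iir` stage per band edge.
#' @export
design_butterworth <- function(spec) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$filter_class != "iir_butterworth")
    stop("spec is not a Butterworth specification", call. = FALSE)
  fs <- spec$sample_rate_hz
  ord <- spec$iir_order_per_edge
  mk <- function(fc, type) {
    ba <- signal::butter(ord, fc / (fs / 2), type = type)
    rts <- polyroot(rev(ba$a))
    if (any(Mod(rts) >= 1 - 1e-10))
      stop("unstable Butterworth design (pole on/outside the unit circle)",
           call. = FALSE)
    list(type = "iir", b = as.numeric(ba$b), a = as.numeric(ba$a),
         cutoff_hz = fc, edge = if (type == "high") "highpass" else "lowpass",
         order = ord)
  }
  stages <- switch(spec$mode,
    lowpass = list(mk(spec$cutoffs_hz, "low")),
    highpass = list(mk(spec$cutoffs_hz, "high")),
    bandpass = list(mk(spec$cutoffs_hz[1], "high"),
                    mk(spec$cutoffs_hz[2], "low")))
  structure(list(spec = spec, stages = stages), class = "designed_filter")
}

#' Design a filter from its specification
#'
#' Dispatches to [design_fir()] or [design_butterworth()].
#' @param spec A [filter_spec()].
#' @return A `designed_filter`.
#' @export
design_filter <- function(spec) {
  switch(spec$filter_class,
         fir_kaiser = design_fir(spec),
         iir_butterworth = design_butterworth(spec))
}

#' Complex frequency response of a designed filter
#'
#' Evaluates the single-pass response at the requested frequencies. For
#' zero-phase (two-pass) IIR application the effective magnitude is the
#' square of this single-pass magnitude.
#'
#' @param filt A `designed_filter`.
#' @param freq_hz Numeric vector of frequencies.
#' @param stage Stage index, or `NULL` for the cascade of all stages.
#' @return Complex vector `H(f)`.
#' @export
filter_response <- function(filt, freq_hz, stage = NULL) {
  fs <- filt$spec$sample_rate_hz
  stages <- if (is.null(stage)) filt$stages else filt$stages[stage]
  H <- rep(1 + 0i, length(freq_hz))
  w <- 2 * pi * freq_hz / fs
  for (st in stages) {
    if (st$type == "fir") {
      k <- seq_along(st$taps) - 1
      Hst <- complex(length(w))
      # chunked so the len(freq) x len(taps) exponential matrix stays small
      idx <- split(seq_along(w), ceiling(seq_along(w) / 256))
      for (ii in idx)
        Hst[ii] <- as.vector(exp(outer(-1i * w[ii], k)) %*% st$taps)
      H <- H * Hst
    } else {
      z <- exp(1i * w)
      num <- outer(z, -(seq_along(st$b) - 1), `^`) %*% st$b
      den <- outer(z, -(seq_along(st$a) - 1), `^`) %*% st$a
      H <- H * as.vector(num / den)
    }
  }
  H
}

#' Measured transition bandwidth of a filter stage
#'
#' Evaluates the realized magnitude response on a dense grid around the
#' stage cutoff and reports the span between the last frequency (on the
#' stopband side) with attenuation at least \eqn{A = -20\log_{10}(\delta)}
#' and the first frequency whose magnitude is within the ripple \eqn{\delta}
#' of the passband target.
#'
#' @param filt A `designed_filter`.
#' @param stage Stage index (default 1).
#' @param grid_hz Grid spacing in Hz (default adapts to the predicted width,
#'   at most 0.01 Hz).
#' @return Transition width in Hz.
#' @export
measure_transition_bw <- function(filt, stage = 1L, grid_hz = NULL) {
  spec <- filt$spec
  st <- filt$stages[[stage]]
  fs <- spec$sample_rate_hz
  nyq <- fs / 2
  ripple <- if (!is.null(spec$ripple)) spec$ripple else 0.001
  pred <- if (!is.null(spec$transition_bw_hz)) spec$transition_bw_hz else
    max(0.05, st$cutoff_hz / 2)
  if (is.null(grid_hz)) grid_hz <- min(0.01, pred / 400)
  lo <- max(0, st$cutoff_hz - 2 * pred)
  hi <- min(nyq, st$cutoff_hz + 2 * pred)
  f <- seq(lo, hi, by = grid_hz)
  mag <- Mod(filter_response(filt, f, stage = stage))
  in_pass <- abs(mag - 1) <= ripple
  in_stop <- mag <= ripple
  if (st$edge == "highpass") {
    f_pass <- f[which(in_pass)[1]]
    f_stop <- max(f[in_stop & f < f_pass])
  } else {
    f_pass <- f[max(which(in_pass))]
    f_stop <- min(f[in_stop & f > f_pass])
  }
  if (!is.finite(f_pass) || !is.finite(f_stop))
    stop("transition edges not found on the evaluation grid", call. = FALSE)
  abs(f_pass - f_stop)
}

# Single zero-phase pass of one stage over a samples x channels matrix.
# FIR: FFT convolution with group-delay compensation (shift by order/2).
# IIR: forward pass, reverse, second pass, reverse, with reflective padding.
apply_stage <- function(st, x, pad = NULL) {
  n <- nrow(x)
  if (st$type == "fir") {
    m <- length(st$taps)
    if (n < m)
      stop("recording shorter than the filter's impulse response", call. = FALSE)
    d <- (m - 1) / 2
    nfft <- stats::nextn(n + m - 1, 2)
    H <- stats::fft(c(st$taps, rep(0, nfft - m)))
    X <- stats::mvfft(rbind(x, matrix(0, nfft - n, ncol(x))))
    y <- Re(stats::mvfft(X * H, inverse = TRUE)) / nfft
    y[(d + 1):(d + n), , drop = FALSE]
  } else {
    ord <- length(st$a) - 1
    if (is.null(pad)) pad <- 3 * ord
    if (n <= pad + 1)
      stop("recording shorter than the two-pass padding requirement", call. = FALSE)
    idx_pre <- (pad + 1):2
    idx_post <- (n - 1):(n - pad)
    xp <- rbind(x[idx_pre, , drop = FALSE], x, x[idx_post, , drop = FALSE])
    one_pass <- function(m) apply(m, 2, function(v)
      as.numeric(signal::filter(st$b, st$a, v)))
    y <- one_pass(xp)
    y <- y[nrow(y):1, , drop = FALSE]
    y <- one_pass(y)
    y <- y[nrow(y):1, , drop = FALSE]
    y[(pad + 1):(pad + n), , drop = FALSE]
  }
}

#' Apply a designed filter with zero-phase semantics
#'
#' FIR stages are applied in a single pass with the group delay (order/2
#' samples) compensated; IIR stages are applied forward-backward (two
#' passes), squaring the magnitude response, with reflective padding of
#' 3 x (stage order) samples at both ends. Stages of a bandpass cascade are
#' applied successively. Output has the shape of the input.
#'
#' @param filt A `designed_filter`.
#' @param x A `continuous_recording`, a channels-free numeric vector, or a
#'   channels x samples matrix.
#' @param pad Override for the IIR reflective padding length (samples).
#' @return Filtered object of the same type as `x`.
#' @export
apply_zero_phase <- function(filt, x, pad = NULL) {
  if (inherits(x, "continuous_recording")) {
    x$data <- apply_zero_phase(filt, x$data, pad = pad)
    return(x)
  }
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, ncol = 1) else t(x)  # samples x channels
  if (any(!is.finite(m)))
    stop("non-finite samples in input", call. = FALSE)
  i <- 1L
  while (i <= length(filt$stages)) {
    if (filt$stages[[i]]$type == "fir") {
      j <- i
      while (j < length(filt$stages) && filt$stages[[j + 1L]]$type == "fir")
        j <- j + 1L
      m <- apply_fir_cascade(filt$stages[i:j], m)
      i <- j + 1L
    } else {
      m <- apply_stage(filt$stages[[i]], m, pad = pad)
      i <- i + 1L
    }
  }
  if (vec) as.numeric(m) else t(m)
}

# One FFT pass for a cascade of FIR stages: multiply stage spectra, then
# compensate the summed group delay.
apply_fir_cascade <- function(stages, x) {
  n <- nrow(x)
  lens <- vapply(stages, function(s) length(s$taps), integer(1))
  if (n < max(lens))
    stop("recording shorter than the filter's impulse response", call. = FALSE)
  total <- sum(lens - 1L) + 1L
  d <- sum((lens - 1L) %/% 2L)
  nfft <- stats::nextn(n + total - 1L, 2)
  H <- rep(1 + 0i, nfft)
  for (s in stages) H <- H * stats::fft(c(s$taps, rep(0, nfft - length(s$taps))))
  X <- stats::mvfft(rbind(x, matrix(0, nfft - n, ncol(x))))
  y <- Re(stats::mvfft(X * H, inverse = TRUE)) / nfft
  y[(d + 1):(d + n), , drop = FALSE]
}

#' Export a designed filter as delimited text plus a JSON response summary
#'
#' FIR stages are written as one tap per line; IIR stages as
#' numerator/denominator coefficient rows. A JSON sidecar records the
#' specification and measured transition widths.
#'
#' @param filt A `designed_filter`.
#' @param path_prefix Output path prefix; files `<prefix>_stage<k>.txt` and
#'   `<prefix>.json` are written.
#' @return Invisibly, the sidecar path.
#' @export
write_filter <- function(filt, path_prefix) {
  for (i in seq_along(filt$stages)) {
    st <- filt$stages[[i]]
    p <- sprintf("%s_stage%d.txt", path_prefix, i)
    if (st$type == "fir") {
      utils::write.table(data.frame(tap = st$taps), p, sep = "\t",
                         row.names = FALSE, quote = FALSE)
    } else {
      utils::write.table(data.frame(b = st$b, a = st$a), p, sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
  }
  side <- sub("\\.json$", "", path_prefix)
  side <- paste0(side, ".json")
  summ <- list(spec = unclass(filt$spec),
               n_stages = length(filt$stages),
               measured_transition_bw_hz = filt$measured_transition_bw_hz)
  jsonlite::write_json(summ, side, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(side)
}

#' @export
print.designed_filter <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<designed_filter> %s %s [%s Hz] fs=%g Hz, %d stage(s)\n",
              s$filter_class, s$mode, paste(s$cutoffs_hz, collapse = "-"),
              s$sample_rate_hz, length(x$stages)))
  if (!is.null(x$measured_transition_bw_hz))
    cat("  measured transition bw (Hz):",
        paste(signif(x$measured_transition_bw_hz, 4), collapse = ", "), "\n")
  invisible(x)
}
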