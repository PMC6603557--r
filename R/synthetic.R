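#' Standard montage labels for the synthetic generator
#'
#' A 62-label 10-10/10-20 montage. Subsets with `n < 62` are spread across
#' the whole scalp (so an average reference behaves like one computed on a
#' full montage) and always contain "F3", "Fp1" and "T7".
#'
#' @param n Number of channels (8..62).
#' @return Character vector of labels.
#' @export
sep_montage <- function(n = 62) {
  labs <- c("Fp1", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
            "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
            "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
            "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
            "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
            "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
            "PO7", "PO5", "PO3", "POz", "PO4", "PO6", "PO8",
            "O1", "Oz", "O2")
  stopifnot(n >= 8, n <= length(labs))
  if (n == length(labs)) return(labs)
  must <- match(c("Fp1", "F3", "T7"), labs)
  idx <- unique(c(must, round(seq(1, length(labs), length.out = n))))
  idx <- sort(idx[seq_len(n)])
  labs[idx]
}

#' Synthetic EEG configuration
#'
#' Defaults mirror the emulated acquisition: 62 channels at 2048 Hz, 1000
#' median-nerve stimuli at 2.3 Hz, an SEP complex with a positive lobe near
#' 20 ms and a negative lobe near 30 ms maximal at F3, 1/f background
#' noise, eye blinks, muscle bursts, 50 Hz line noise, a biphasic stimulus
#' artifact inside +/-1 ms, and occasionally flat channels. Lobes are
#' Gaussian with `width_ms` interpreted as full width at half maximum, so
#' their spectral content is concentrated well below 100 Hz with
#' substantial energy below 30 Hz.
#'
#' @param n_channels,sample_rate_hz,n_stimuli,stim_rate_hz Acquisition
#'   geometry.
#' @param sep_pos_uv,sep_neg_uv Lobe amplitudes (microvolts) at F3; the
#'   noiseless peak-to-peak N30 is `sep_pos_uv - sep_neg_uv`.
#' @param sep_pos_ms,sep_neg_ms,sep_width_ms Lobe centers and FWHM (ms).
#' @param amplitude_scale Multiplicative SEP scale (e.g. a subject's random
#'   intercept on the amplitude).
#' @param noise_rms_uv,noise_exponent 1/f background noise RMS and spectral
#'   exponent (power ~ 1/f^exponent).
#' @param blink_rate_per_min,blink_amplitude_uv Eye-blink pulse rate and
#'   peak amplitude (frontal topography).
#' @param muscle_rate_per_min,muscle_amplitude_uv,muscle_band_hz Muscle
#'   burst rate, RMS amplitude and frequency band.
#' @param muscle_reflex_uv Amplitude (at full muscle loading) of the
#'   stimulus-locked muscle reflex artifact: a biphasic lobe pair (positive
#'   near 18 ms, negative near 32 ms) evoked by every stimulus, emulating
#'   the stimulation-evoked scalp EMG reflex that overlaps the SEP complex.
#'   Because it is phase-locked it survives averaging; it belongs to the
#'   muscle source, so component removal eliminates it.
#' @param line_hz,line_amplitude_uv Mains frequency and amplitude.
#' @param stim_artifact_uv Stimulus-artifact spike amplitude.
#' @param n_flat_channels Number of (non-F3) channels rendered flat.
#' @param seed Integer seed; fully determines the output.
#' @return A `synth_config` object.
#' @export
synth_config <- function(n_channels = 62, sample_rate_hz = 2048,
                         n_stimuli = 1000, stim_rate_hz = 2.3,
                         sep_pos_uv = 1.5, sep_neg_uv = -2.0,
                         sep_pos_ms = 20, sep_neg_ms = 30, sep_width_ms = 5,
                         amplitude_scale = 1,
                         noise_rms_uv = 8, noise_exponent = 1,
                         blink_rate_per_min = 15, blink_amplitude_uv = 350,
                         muscle_rate_per_min = 4, muscle_amplitude_uv = 30,
                         muscle_band_hz = c(20, 300), muscle_reflex_uv = 2,
                         line_hz = 50, line_amplitude_uv = 5,
                         stim_artifact_uv = 100,
                         n_flat_channels = 1,
                         seed = 1) {
  cfg <- as.list(environment())
  if (sep_pos_ms <= -100 || sep_neg_ms >= 150)
    stop("SEP template lobes must lie inside the epoch window", call. = FALSE)
  rates <- c(blink_rate_per_min, muscle_rate_per_min, line_amplitude_uv,
             blink_amplitude_uv, muscle_amplitude_uv, noise_rms_uv,
             stim_artifact_uv)
  if (any(rates < 0)) stop("rates and amplitudes must be non-negative", call. = FALSE)
  structure(cfg, class = "synth_config")
}

# Topography (per-channel loading) for one source type. Deterministic,
# driven only by the channel labels.
source_topography <- function(labels, type) {
  w <- rep(0.05, length(labels))
  names(w) <- labels
  set <- function(labs, val) {
    hit <- intersect(labs, labels)
    w[hit] <<- val
  }
  switch(type,
    sep = {
      set(c("AF3", "AF7", "AFz", "Fp1"), 0.3)
      set(c("Fz", "F1", "F5", "F7", "FC1", "C3", "C1"), 0.4)
      set(c("FC3", "FC5"), 0.55)
      set("F3", 1.0)
    },
    blink = {
      set(c("F1", "F3", "F5", "Fz", "F2", "F4", "F6"), 0.4)
      set(c("F7", "F8"), 0.45)
      set(c("AF7", "AF3", "AFz", "AF4", "AF8"), 0.7)
      set(c("Fp1", "Fp2"), 1.0)
      set(c("FC1", "FC3", "FC5", "FCz", "FC2", "FC4", "FC6"), 0.15)
    },
    muscle = {
      set(c("F5", "F6"), 0.3)
      set(c("F7", "F8"), 0.6)
      set(c("T7", "T8", "FT7", "FT8", "TP7", "TP8"), 1.0)
      set("F3", 0.4)   # frontal EMG; keeps the post-average-reference loading positive
    },
    line = {
      w[] <- 1 + 0.1 * sin(seq_along(labels))
    },
    stim = {
      w[] <- 0.5
    })
  unname(w)
}

# 1/f^(exponent) spectral shaping of white noise, scaled to target RMS.
one_over_f_noise <- function(n, exponent, rms) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(0, seq_len(n - 1))
  f <- pmin(f, n - f)                     # two-sided bin index
  scale <- pmax(f, 1)^(-exponent / 2)
  scale[1] <- 0
  y <- Re(stats::fft(X * scale, inverse = TRUE)) / n
  y * rms / stats::sd(y)
}

# Gaussian SEP kernel sampled at offsets 0..support (samples), FWHM widths.
sep_kernel <- function(cfg) {
  fs <- cfg$sample_rate_hz
  supp <- as.integer(round(0.050 * fs))
  t_ms <- (0:supp) / fs * 1000
  sd_ms <- cfg$sep_width_ms / (2 * sqrt(2 * log(2)))
  cfg$amplitude_scale *
    (cfg$sep_pos_uv * exp(-(t_ms - cfg$sep_pos_ms)^2 / (2 * sd_ms^2)) +
     cfg$sep_neg_uv * exp(-(t_ms - cfg$sep_neg_ms)^2 / (2 * sd_ms^2)))
}

#' Generate a synthetic continuous EEG recording with ground truth
#'
#' Builds `recording = mixing %*% sources` over the good channels, where the
#' sources are: the stimulus-locked SEP complex, a biphasic stimulus
#' artifact confined to +/-1 ms around each onset, an eye-blink pulse train
#' (frontal), band-limited muscle bursts (temporal, with a small F3
#' loading), a mains sinusoid, and one 1/f background source per remaining
#' channel. The mixing matrix is square and invertible on the good
#' channels, so the returned ICA model (its exact inverse, with true
#' labels) reconstructs and removes sources exactly. Flat channels are
#' excluded from the model and stay exactly constant (dead electrodes).
#' Identical
#' seeds give identical output; each source type draws from its own
#' RNG stream split from the master seed.
#'
#' @param cfg A [synth_config()].
#' @param keep_sources Keep the source matrix in the ground truth (memory!).
#' @return List with elements `recording` (`continuous_recording`),
#'   `ground_truth` (epoch labels, flat channels, mixing, true N30, event
#'   cores) and `ica_model` (true unmixing with labels).
#' @export
generate_recording <- function(cfg, keep_sources = TRUE) {
  stopifnot(inherits(cfg, "synth_config"))
  fs <- cfg$sample_rate_hz
  labels <- sep_montage(cfg$n_channels)
  set.seed(cfg$seed)
  stream <- sample.int(.Machine$integer.max %/% 2L, 8)

  isi <- fs / cfg$stim_rate_hz
  onsets <- as.integer(round(2 * fs + (seq_len(cfg$n_stimuli) - 1) * isi))
  n <- onsets[length(onsets)] + as.integer(2 * fs)

  # flat channels (never F3)
  set.seed(stream[1])
  flat <- character(0)
  if (cfg$n_flat_channels > 0) {
    cand <- setdiff(labels, "F3")
    flat <- sample(cand, min(cfg$n_flat_channels, length(cand)))
  }
  good <- setdiff(labels, flat)
  g <- length(good)
  if (g < 6L) stop("too few good channels for the source model", call. = FALSE)

  # --- sources ----------------------------------------------------------
  kern <- sep_kernel(cfg)
  src_sep <- numeric(n)
  for (o in onsets) {
    idx <- o:(o + length(kern) - 1L)
    src_sep[idx] <- src_sep[idx] + kern
  }

  w1 <- as.integer(round(fs / 1000))   # 1 ms
  src_stim <- numeric(n)
  for (o in onsets) {
    src_stim[o:(o + w1 - 1L)] <- cfg$stim_artifact_uv
    src_stim[(o + w1):(o + 2L * w1 - 1L)] <- -cfg$stim_artifact_uv
  }

  dur_min <- n / fs / 60
  set.seed(stream[2])
  src_blink <- numeric(n)
  blink_cores <- matrix(numeric(0), ncol = 2)
  n_blink <- stats::rpois(1, cfg$blink_rate_per_min * dur_min)
  if (n_blink > 0 && cfg$blink_amplitude_uv > 0) {
    centers <- sort(sample.int(n, n_blink))
    sd_s <- 0.060
    half <- as.integer(round(3 * sd_s * fs))
    tt <- (-half):half
    bump <- exp(-(tt / fs)^2 / (2 * sd_s^2))
    amps <- cfg$blink_amplitude_uv * stats::runif(n_blink, 0.8, 1.25)
    fwhm <- as.integer(round(sd_s * fs * sqrt(2 * log(2))))
    cores <- matrix(0, n_blink, 2)
    for (b in seq_len(n_blink)) {
      idx <- centers[b] + tt
      sel <- idx >= 1L & idx <= n
      src_blink[idx[sel]] <- src_blink[idx[sel]] + amps[b] * bump[sel]
      cores[b, ] <- c(max(1L, centers[b] - fwhm), min(n, centers[b] + fwhm))
    }
    blink_cores <- cores
  }

  set.seed(stream[3])
  src_muscle <- numeric(n)
  muscle_cores <- matrix(numeric(0), ncol = 2)
  n_burst <- stats::rpois(1, cfg$muscle_rate_per_min * dur_min)
  if (n_burst > 0 && cfg$muscle_amplitude_uv > 0) {
    centers <- sort(sample.int(n, n_burst))
    L <- as.integer(round(0.3 * fs))
    env <- 0.5 * (1 - cos(2 * pi * seq_len(L) / (L + 1)))   # Hann
    fb <- seq(0, fs, length.out = L + 1)[seq_len(L)]
    fb <- pmin(fb, fs - fb)
    band <- fb >= cfg$muscle_band_hz[1] & fb <= cfg$muscle_band_hz[2]
    cores <- matrix(0, n_burst, 2)
    for (b in seq_len(n_burst)) {
      wn <- stats::rnorm(L)
      W <- stats::fft(wn)
      W[!band] <- 0
      burst <- Re(stats::fft(W, inverse = TRUE)) / L
      burst <- burst / stats::sd(burst) * cfg$muscle_amplitude_uv * env
      idx <- centers[b] + seq_len(L) - L %/% 2L
      sel <- idx >= 1L & idx <= n
      src_muscle[idx[sel]] <- src_muscle[idx[sel]] + burst[sel]
      core <- range(idx[sel][env[sel] > 0.5])
      cores[b, ] <- core
    }
    muscle_cores <- cores
  }
  if (cfg$muscle_reflex_uv > 0) {
    # stimulus-locked reflex: biphasic lobes overlapping the SEP windows
    supp <- as.integer(round(0.050 * fs))
    tr_ms <- (0:supp) / fs * 1000
    sd_ms <- 4 / (2 * sqrt(2 * log(2)))
    rker <- cfg$muscle_reflex_uv *
      (exp(-(tr_ms - 18)^2 / (2 * sd_ms^2)) -
         exp(-(tr_ms - 32)^2 / (2 * sd_ms^2)))
    for (o in onsets) {
      idx <- o:(o + supp)
      src_muscle[idx] <- src_muscle[idx] + rker
    }
  }

  set.seed(stream[4])
  phase <- stats::runif(1, 0, 2 * pi)
  src_line <- cfg$line_amplitude_uv * sin(2 * pi * cfg$line_hz *
                                            seq_len(n) / fs + phase)

  set.seed(stream[5])
  n_bg <- g - 5L
  src_bg <- matrix(0, n_bg, n)
  if (cfg$noise_rms_uv > 0)
    for (k in seq_len(n_bg))
      src_bg[k, ] <- one_over_f_noise(n, cfg$noise_exponent, cfg$noise_rms_uv)

  sources <- rbind(src_sep, src_stim, src_blink, src_muscle, src_line, src_bg)
  src_labels <- c("brain", "channel_noise", "eye", "muscle", "line_noise",
                  rep("brain", n_bg))
  rownames(sources) <- c("sep", "stim", "blink", "muscle", "line",
                         paste0("bg", seq_len(n_bg)))

  # --- mixing (square, diagonally dominant background block) ------------
  set.seed(stream[6])
  topo <- cbind(sep = source_topography(good, "sep"),
                stim = source_topography(good, "stim"),
                blink = source_topography(good, "blink"),
                muscle = source_topography(good, "muscle"),
                line = source_topography(good, "line"))
  B <- matrix(0, g, n_bg)
  B[cbind(5L + seq_len(n_bg), seq_len(n_bg))] <- 1
  B <- B + matrix(0.03 * stats::rnorm(g * n_bg), g, n_bg)
  mixing <- cbind(topo, B)
  rownames(mixing) <- good
  colnames(mixing) <- rownames(sources)
  unmixing <- solve(mixing)

  data <- matrix(0, cfg$n_channels, n)
  rownames(data) <- labels
  data[good, ] <- mixing %*% sources
  # flat channels stay exactly constant (dead electrode)

  rec <- continuous_recording(data, fs, labels, events = onsets)

  # --- ground truth -----------------------------------------------------
  n_pre <- as.integer(round(0.100 * fs))
  n_post <- as.integer(round(0.150 * fs))
  overlaps <- function(cores, o) {
    if (!nrow(cores)) return(FALSE)
    any(cores[, 1] <= o + n_post - 1L & cores[, 2] >= o - n_pre)
  }
  epoch_labels <- lapply(onsets, function(o) {
    lab <- character(0)
    if (overlaps(blink_cores, o)) lab <- c(lab, "eye")
    if (overlaps(muscle_cores, o)) lab <- c(lab, "muscle")
    lab
  })

  t_ms <- (0:(length(kern) - 1L)) / fs * 1000
  true_n30 <- max(kern[t_ms >= 15 & t_ms <= 25]) -
    min(kern[t_ms >= 25 & t_ms <= 35])

  model <- ica_model(unmixing, labels = src_labels, channel_subset = good,
                     mixing = mixing)
  gt <- list(epoch_labels = epoch_labels, flat_channels = flat,
             mixing = mixing, source_labels = src_labels,
             true_n30_uv = true_n30,
             blink_cores = blink_cores, muscle_cores = muscle_cores,
             onsets = onsets)
  if (keep_sources) gt$sources <- sources
  list(recording = rec, ground_truth = gt, ica_model = model)
}
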