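# Small shared synthetic datasets, generated once per test run.
small_cfg <- function(seed = 3, ...) {
  args <- list(n_channels = 16, n_stimuli = 60, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synth_config, args)
}

.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(seed = 3) {
  key <- paste0("s", seed)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- generate_recording(small_cfg(seed))
  .sim_cache[[key]]
}

# A clean recording: no artifacts, no noise, no flat channels.
clean_cfg <- function(seed = 1, ...) {
  small_cfg(seed = seed, noise_rms_uv = 0, blink_rate_per_min = 0,
            muscle_rate_per_min = 0, muscle_reflex_uv = 0,
            line_amplitude_uv = 0, stim_artifact_uv = 0,
            n_flat_channels = 0, ...)
}

# Epochs on a 512 Hz grid: 128 samples spanning -100..150 ms.
art_epoch_set <- function(traces, fs = 512) {
  n <- length(traces)
  arr <- array(0, c(n, 1, length(traces[[1]])))
  for (i in seq_len(n)) arr[i, 1, ] <- traces[[i]]
  epoch_set(arr, time_ms = ((-51):(length(traces[[1]]) - 52)) / fs * 1000,
            sample_rate_hz = fs, channel_labels = "F3")
}

art_mask <- function(ep) ep$time_ms >= -2 & ep$time_ms <= 2

# Adversarial random traces exercising every rule regime.
random_traces <- function(n, len = 128, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    kind <- sample(5, 1)
    tr <- switch(kind,
      rnorm(len, 0, 40),                       # near p2p/abs thresholds
      rnorm(len, 0, 0.8),                      # near-flat
      cumsum(rnorm(len, 0, 15)),               # drifts (step rule)
      rnorm(len, 0, 20) + c(rep(0, 64), rep(runif(1, 50, 150), len - 64)),
      { x <- rnorm(len, 0, 10)                 # isolated spikes
        x[sample(len, 3)] <- runif(3, 60, 160) * sample(c(-1, 1), 3, TRUE)
        x })
    tr
  })
}
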