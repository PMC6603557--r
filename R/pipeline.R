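#' The three passbands of the comparison
#'
#' @return Named list of `c(low, high)` cutoffs in Hz.
#' @export
sep_bands <- function() {
  list("0.5-1000" = c(0.5, 1000),
       "3-1000" = c(3, 1000),
       "30-1000" = c(30, 1000))
}

# Design the class-specific filters used by the pipeline.
pipeline_filters <- function(fs, classes, bands, fir_order_bp = 7420L,
                             fir_order_hp = 4948L) {
  out <- list()
  for (cl in classes) {
    if (cl == "FIR") {
      hp <- design_fir(filter_spec("fir_kaiser", "highpass", 1, fs,
                                   fir_order = fir_order_hp))
      bp <- lapply(bands, function(b)
        design_fir(filter_spec("fir_kaiser", "bandpass", b, fs,
                               fir_order = fir_order_bp)))
    } else {
      hp <- design_butterworth(filter_spec("iir_butterworth", "highpass", 1, fs))
      bp <- lapply(bands, function(b)
        design_butterworth(filter_spec("iir_butterworth", "bandpass", b, fs)))
    }
    out[[cl]] <- list(hp = hp, bp = bp)
  }
  out
}

#' Run the filter-class x passband x ICA condition grid on one dataset
#'
#' Executes the full comparison on a (typically synthetic) recording with a
#' known ICA model: truncation and the standardization stage once; then per
#' filter class, artifact detection on 1 Hz high-pass filtered epochs; then
#' per passband, zero-phase band-pass filtering of the standardized data,
#' epoching, baseline correction, and N30 measurement of the good-epoch
#' average both without ICA and after removal of the non-brain components.
#'
#' @param sim Output of [generate_recording()], or a list with elements
#'   `recording` and `ica_model`.
#' @param classes Filter classes to run (`"FIR"`, `"IIR"` or both).
#' @param bands Named list of passbands (default [sep_bands()]).
#' @param fir_order_bp,fir_order_hp FIR orders for the band-pass (7420) and
#'   the detection high-pass (4948).
#' @param channel Measurement channel (default `"F3"`).
#' @param rules An [artifact_rules()] object.
#' @param line_hz Line frequency handed to the standardization stage.
#' @param filters Optional precomputed [pipeline_filters()] designs (reused
#'   across seeds to avoid redesigning identical filters).
#' @return `data.frame` with one row per condition: `filter`, `band`,
#'   `ica`, `n30_amplitude_uv`, `n_good`, `n_artifacts`.
#' @export
run_condition_grid <- function(sim, classes = c("FIR", "IIR"),
                               bands = sep_bands(),
                               fir_order_bp = 7420L, fir_order_hp = 4948L,
                               channel = "F3", rules = artifact_rules(),
                               line_hz = 50, filters = NULL) {
  rec <- truncate_recording(sim$recording)
  prep <- run_prep(rec, line_hz = line_hz)
  fs <- prep$sample_rate_hz
  model <- rereference_ica_model(sim$ica_model)
  if (is.null(filters))
    filters <- pipeline_filters(fs, classes, bands, fir_order_bp, fir_order_hp)
  rows <- list()
  for (cl in classes) {
    det <- apply_zero_phase(filters[[cl]]$hp, prep)
    ep_det <- baseline_correct(extract_epochs(det))
    ep_det <- detect_artifacts(ep_det, rules)
    flags <- ep_det$artifact_flags
    n_art <- count_artifacts(ep_det)
    for (bn in names(bands)) {
      filtered <- apply_zero_phase(filters[[cl]]$bp[[bn]], prep)
      ep <- baseline_correct(extract_epochs(filtered))
      if (n_epochs(ep) != length(flags))
        stop("detection and measurement epoch counts differ", call. = FALSE)
      ep$artifact_flags <- flags
      good <- subset_epochs(ep, good_epochs(ep))
      m_no <- n30_from_epochs(good, channel = channel)
      cleaned <- remove_components(good, model)
      m_yes <- n30_from_epochs(cleaned, channel = channel)
      rows[[length(rows) + 1L]] <- data.frame(
        filter = cl, band = bn, ica = c("no", "yes"),
        n30_amplitude_uv = c(m_no$amplitude_uv, m_yes$amplitude_uv),
        n_good = n_epochs(good), n_artifacts = n_art)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a cohort and collect the condition grid per dataset
#'
#' Generates one synthetic recording per (subject, session) dataset --
#' subjects carry a log-normal random intercept on the SEP amplitude --
#' runs the condition grid on each, and stacks the per-condition N30
#' amplitudes into the input format of [fit_gamma_lmm()].
#'
#' @param n_subjects,n_sessions Cohort size.
#' @param cfg Base [synth_config()] (its `amplitude_scale` and `seed` are
#'   overridden per dataset).
#' @param sigma_subject SD of the subject random intercept on the log
#'   amplitude scale (default 0.3).
#' @param seed Master seed.
#' @param ... Passed to [run_condition_grid()].
#' @return `data.frame` with columns `subject_id`, `dataset_id`, `filter`,
#'   `band`, `ica`, `n30_amplitude_uv`, `n_good`, `n_artifacts`.
#' @export
simulate_cohort_grid <- function(n_subjects, n_sessions, cfg,
                                 sigma_subject = 0.3, seed = 1, ...) {
  set.seed(seed)
  subj_scale <- exp(stats::rnorm(n_subjects, 0, sigma_subject))
  dataset_seeds <- sample.int(2^30, n_subjects * n_sessions)
  filters <- NULL
  out <- list()
  k <- 0L
  for (i in seq_len(n_subjects)) {
    for (j in seq_len(n_sessions)) {
      k <- k + 1L
      cfg_ij <- cfg
      cfg_ij$amplitude_scale <- cfg$amplitude_scale * subj_scale[i]
      cfg_ij$seed <- dataset_seeds[k]
      sim <- generate_recording(cfg_ij, keep_sources = FALSE)
      args <- list(...)
      if (is.null(filters)) {
        classes <- if (is.null(args$classes)) c("FIR", "IIR") else args$classes
        bands <- if (is.null(args$bands)) sep_bands() else args$bands
        filters <- pipeline_filters(sim$recording$sample_rate_hz, classes, bands)
      }
      grid <- do.call(run_condition_grid,
                      c(list(sim = sim, filters = filters), args))
      grid$subject_id <- sprintf("S%02d", i)
      grid$dataset_id <- sprintf("S%02d_D%d", i, j)
      out[[k]] <- grid
    }
  }
  res <- do.call(rbind, out)
  res[, c("subject_id", "dataset_id", "filter", "band", "ica",
          "n30_amplitude_uv", "n_good", "n_artifacts")]
}
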