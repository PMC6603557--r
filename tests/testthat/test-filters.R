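test_that("Kaiser beta mapping follows the attenuation formula", {
  expect_equal(round(kaiser_beta_from_ripple(0.001), 3), 5.653)
  expect_equal(kaiser_beta_from_ripple(0.1), 0)           # A = 20 dB < 21
  expect_equal(kaiser_beta_from_ripple(0.0001), 0.1102 * (80 - 8.7))
  expect_error(kaiser_beta_from_ripple(0), "inside")
  expect_error(kaiser_beta_from_ripple(1.2), "inside")
})

test_that("FIR order is inversely proportional to the transition bandwidth", {
  o1 <- fir_order_from_transition(1, 2048)
  o15 <- fir_order_from_transition(1.5, 2048)
  expect_lt(abs(o1 - 7420) / 7420, 0.002)
  expect_lt(abs(o15 - 4948) / 4948, 0.002)
  expect_true(o1 %% 2 == 0 && o15 %% 2 == 0)
  # halving the bandwidth doubles the order (within even rounding)
  o2 <- fir_order_from_transition(0.5, 2048)
  expect_lte(abs(o2 - 2 * o1), 2)
  expect_error(fir_order_from_transition(-1, 2048), "positive")
})

test_that("windowed-sinc designs are linear phase with -6 dB cutoffs", {
  fs <- 2048
  lp <- design_fir(filter_spec("fir_kaiser", "lowpass", 1000, fs,
                               fir_order = 7420))
  expect_equal_tol(Mod(filter_response(lp, 1000)), 0.5, 0.01)
  taps <- lp$stages[[1]]$taps
  expect_equal(taps, rev(taps))                           # symmetric
  expect_equal_tol(sum(taps), 1, 0.001)                   # DC gain

  hp <- design_fir(filter_spec("fir_kaiser", "highpass", 1, fs,
                               fir_order = 7420))
  expect_lt(abs(sum(hp$stages[[1]]$taps)), 1e-6)          # DC null
  expect_equal(hp$stages[[1]]$taps, rev(hp$stages[[1]]$taps))
  expect_equal_tol(hp$measured_transition_bw_hz, 1.0, 0.05)

  expect_error(design_fir(filter_spec("fir_kaiser", "lowpass", 100, fs,
                                      fir_order = 101)), "even")
})

test_that("Butterworth designs have half-power cutoffs, monotone magnitude", {
  fs <- 2048
  hp <- design_butterworth(filter_spec("iir_butterworth", "highpass", 1, fs))
  expect_equal_tol(Mod(filter_response(hp, 1)), 2^(-0.5), 1e-3)
  # forward-backward application squares the magnitude: gain 0.5 at cutoff
  fs2 <- 512
  hp2 <- design_butterworth(filter_spec("iir_butterworth", "highpass", 1, fs2))
  t <- seq_len(16 * fs2) / fs2
  y <- apply_zero_phase(hp2, sin(2 * pi * t))
  gain <- fit_sinusoid(y[(4 * fs2):(12 * fs2)], 1, fs2)$amplitude
  expect_equal_tol(gain, 0.5, 1e-3)
  # strictly monotone magnitude through the transition
  g <- Mod(filter_response(hp, seq(0.05, 50, by = 0.05)))
  expect_true(all(diff(g) > -1e-12))
  lp <- design_butterworth(filter_spec("iir_butterworth", "lowpass", 100, fs))
  gl <- Mod(filter_response(lp, seq(1, 1000, by = 1)))
  expect_true(all(diff(gl) < 1e-12))
  # H(z = 1) = 0 for the highpass
  expect_lt(Mod(filter_response(hp, 0)), 1e-10)
})

test_that("zero-phase application preserves passband sinusoids without lag", {
  fs <- 2048
  t <- seq_len(8 * fs) / fs
  x <- sin(2 * pi * 10 * t)
  mid <- 4000:12000
  for (cl in c("fir_kaiser", "iir_butterworth")) {
    spec <- filter_spec(cl, "bandpass", c(0.5, 1000), fs, fir_order = 3000)
    y <- apply_zero_phase(design_filter(spec), x)
    fit <- fit_sinusoid(y[mid], 10, fs)
    expect_equal_tol(fit$amplitude, 1, 0.01)
    # phase relative to the input sinusoid (input phase is 0 by construction)
    expect_lt(abs(fit$phase - fit_sinusoid(x[mid], 10, fs)$phase) * 180 / pi,
              0.5)
  }
})

test_that("stopband sinusoids are attenuated as the realized response predicts", {
  fs <- 2048
  t <- seq_len(8 * fs) / fs
  x5 <- sin(2 * pi * 5 * t)
  bp <- design_fir(filter_spec("fir_kaiser", "bandpass", c(30, 1000), fs,
                               fir_order = 7420))
  y <- apply_zero_phase(bp, x5)
  att <- fit_sinusoid(y[5000:11000], 5, fs)$amplitude
  expect_lt(att, 0.01)
  expect_lt(att, Mod(filter_response(bp, 5)) + 1e-4)   # realized-response oracle
})

test_that("two-pass IIR equals the literal filter-reverse-filter-reverse oracle", {
  fs <- 512
  set.seed(11)
  x <- cumsum(rnorm(2000))
  hp <- design_butterworth(filter_spec("iir_butterworth", "highpass", 2, fs))
  st <- hp$stages[[1]]
  y <- apply_zero_phase(hp, x)
  y_oracle <- oracle_filtfilt(st$b, st$a, x, pad = 3 * (length(st$a) - 1))
  expect_equal(y, y_oracle, tolerance = 1e-12)
})

test_that("degenerate filtering inputs error cleanly", {
  fs <- 2048
  f <- design_fir(filter_spec("fir_kaiser", "lowpass", 100, fs, fir_order = 500))
  expect_error(apply_zero_phase(f, rnorm(100)), "impulse response")
  expect_error(apply_zero_phase(f, c(rnorm(600), NA)), "finite")
  expect_error(filter_spec("fir_kaiser", "bandpass", c(10), fs, fir_order = 10),
               "two cutoffs")
  expect_error(filter_spec("fir_kaiser", "lowpass", 2000, fs, fir_order = 10),
               "Nyquist")
  expect_error(filter_spec("fir_kaiser", "lowpass", 100, fs), "needs")
})

test_that("filter export writes taps and a JSON response summary", {
  fs <- 2048
  f <- design_fir(filter_spec("fir_kaiser", "lowpass", 100, fs, fir_order = 64))
  pre <- file.path(withr::local_tempdir(), "flt")
  write_filter(f, pre)
  taps <- read.delim(paste0(pre, "_stage1.txt"))$tap
  expect_equal(taps, f$stages[[1]]$taps)
  js <- jsonlite::read_json(paste0(pre, ".json"), simplifyVector = TRUE)
  expect_equal(js$spec$fir_order, 64)
})
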