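# Independent brute-force oracles used to validate the optimized
# implementations. Deliberately literal: nested loops straight from the
# rule definitions, no shared code with the package internals.

oracle_window_starts <- function(n, win, step) {
  s <- seq(1L, n - win + 1L, by = step)
  if (s[length(s)] != n - win + 1L) s <- c(s, n - win + 1L)
  s
}

# Evaluate all five artifact rules on one trace; returns the violated set.
oracle_rules <- function(trace, fs, mask, rules = artifact_rules()) {
  n <- length(trace)
  hit <- character(0)
  um <- which(!mask)
  if (any(abs(trace[um]) > rules$abs_thresh_uv)) hit <- c(hit, "abs")

  win <- round(rules$p2p_window_ms / 1000 * fs)
  best <- -Inf
  for (s in oracle_window_starts(n, win, round(rules$p2p_step_ms / 1000 * fs))) {
    v <- c()
    for (k in s:(s + win - 1L)) if (!mask[k]) v <- c(v, trace[k])
    if (length(v) >= 2) best <- max(best, max(v) - min(v))
  }
  if (best > rules$p2p_thresh_uv) hit <- c(hit, "p2p")

  win <- round(rules$step_window_ms / 1000 * fs)
  half <- win %/% 2L
  best <- -Inf
  for (s in oracle_window_starts(n, win, round(rules$step_step_ms / 1000 * fs))) {
    v1 <- c(); v2 <- c()
    for (k in s:(s + half - 1L)) if (!mask[k]) v1 <- c(v1, trace[k])
    for (k in (s + half):(s + win - 1L)) if (!mask[k]) v2 <- c(v2, trace[k])
    if (length(v1) && length(v2)) best <- max(best, abs(mean(v2) - mean(v1)))
  }
  if (best > rules$step_thresh_uv) hit <- c(hit, "step")

  for (k in seq_len(n - 1L))
    if (!mask[k] && !mask[k + 1L] &&
        abs(trace[k + 1L] - trace[k]) > rules$s2s_thresh_uv) {
      hit <- c(hit, "s2s")
      break
    }

  run <- 0L; best_run <- 0L
  for (k in seq_len(n)) {
    if (!mask[k] && abs(trace[k]) < rules$flat_thresh_uv) {
      run <- run + 1L
      best_run <- max(best_run, run)
    } else run <- 0L
  }
  if (best_run / fs * 1000 > rules$flat_min_dur_ms) hit <- c(hit, "flat")

  sort(hit)
}

# Literal two-pass IIR: reflect-pad, recurse forward (direct form), reverse,
# recurse again, reverse, trim. Recursion written out by hand.
oracle_filtfilt <- function(b, a, x, pad) {
  recurse <- function(x) {
    y <- numeric(length(x))
    for (t in seq_along(x)) {
      acc <- 0
      for (k in seq_along(b)) if (t - k + 1 >= 1) acc <- acc + b[k] * x[t - k + 1]
      for (k in seq_along(a)[-1]) if (t - k + 1 >= 1) acc <- acc - a[k] * y[t - k + 1]
      y[t] <- acc / a[1]
    }
    y
  }
  n <- length(x)
  xp <- c(x[(pad + 1):2], x, x[(n - 1):(n - pad)])
  y <- rev(recurse(rev(recurse(xp))))
  y[(pad + 1):(pad + n)]
}

# Amplitude and phase of a sinusoid at frequency f in a trace, by least
# squares on sine/cosine regressors.
fit_sinusoid <- function(x, f, fs) {
  t <- seq_along(x) / fs
  X <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
  cf <- qr.solve(X, x)
  list(amplitude = sqrt(sum(cf^2)), phase = atan2(cf[2], cf[1]))
}

expect_equal_tol <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("|%g - %g| <= %g", object, expected, tol))
}
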