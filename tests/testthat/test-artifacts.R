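test_that("all five rules match the literal brute-force oracle on random epochs", {
  traces <- random_traces(80, seed = 7)
  ep <- detect_artifacts(art_epoch_set(traces))
  mask <- art_mask(art_epoch_set(traces))
  for (i in seq_along(traces)) {
    expect_identical(ep$artifact_flags[[i]],
                     oracle_rules(traces[[i]], 512, mask),
                     label = paste("epoch", i))
  }
})

test_that("constructed epochs are flagged exactly as the rule definitions dictate", {
  fs <- 512
  len <- 128
  zero <- rep(0, len)
  spike50 <- zero; spike50[which.min(abs(((-51):76) / fs * 1000 - 50))] <- 101
  spike_in_mask <- zero
  spike_in_mask[which.min(abs(((-51):76) / fs * 1000 - 1))] <- 101
  square <- c(rep(0, 64), rep(60, 64))        # 60 uV step at mid-epoch
  ep <- detect_artifacts(art_epoch_set(list(zero, spike50, spike_in_mask, square)))
  mask <- art_mask(art_epoch_set(list(zero)))
  # all-zero epoch: only the flatline rule fires
  expect_identical(ep$artifact_flags[[1]], "flat")
  # 101 uV spike at 50 ms: abs and sample-to-sample jump (oracle-confirmed)
  expect_identical(ep$artifact_flags[[2]], oracle_rules(spike50, fs, mask))
  expect_true(all(c("abs", "s2s") %in% ep$artifact_flags[[2]]))
  # the same spike inside the exclusion window never fires abs/p2p/step/s2s
  expect_false(any(c("abs", "p2p", "step", "s2s") %in% ep$artifact_flags[[3]]))
  # slow square wave: step rule (half-window mean difference 60 < 100 is not
  # enough; 120 uV swing is) -- oracle decides
  expect_identical(ep$artifact_flags[[4]], oracle_rules(square, fs, mask))
})

test_that("window statistics match closed forms", {
  fs <- 512
  saw <- seq(-80, 80, length.out = 102)       # spans one 200 ms window
  expect_equal(sliding_p2p(saw, 200, 100, fs), 160)
  expect_equal(sliding_p2p(rep(3, 128), 200, 100, fs), 0)
  # a step sitting exactly at a grid window's half boundary reads out fully
  stepped <- c(rep(0, 51), rep(120, 77))
  expect_equal(step_statistic(stepped, 200, 50, fs), 120)
  # linear ramp of total rise r within one window gives r / 2
  ramp <- seq(0, 90, length.out = 102)
  expect_equal_tol(step_statistic(ramp, 200, 50, fs), 45, 0.5)
  expect_equal(step_statistic(rep(5, 128), 200, 50, fs), 0)
  # random trace: equals exhaustive evaluation on the step grid
  set.seed(8)
  tr <- rnorm(128, 0, 30)
  mask <- rep(FALSE, 128)
  expect_equal(sliding_p2p(tr, 80, 40, fs, mask), {
    win <- round(0.080 * fs); best <- -Inf
    for (s in oracle_window_starts(128, win, round(0.040 * fs)))
      best <- max(best, diff(range(tr[s:(s + win - 1)])))
    best
  })
})

test_that("raising any threshold never increases the flagged count", {
  traces <- random_traces(40, seed = 9)
  base <- artifact_rules()
  n0 <- count_artifacts(detect_artifacts(art_epoch_set(traces), base))
  for (par in c("abs_thresh_uv", "p2p_thresh_uv", "step_thresh_uv",
                "s2s_thresh_uv")) {
    r <- base
    r[[par]] <- r[[par]] * 1.5
    expect_lte(count_artifacts(detect_artifacts(art_epoch_set(traces), r)), n0)
  }
  # flat rule: raising the duration (not amplitude) threshold is the
  # conservative direction
  r <- base; r$flat_min_dur_ms <- 200
  expect_lte(count_artifacts(detect_artifacts(art_epoch_set(traces), r)), n0)
})

test_that("contamination confined to the exclusion window never triggers any rule", {
  fs <- 512
  len <- 128
  tms <- ((-51):76) / fs * 1000
  inside <- which(tms >= -2 & tms <= 2)
  set.seed(10)
  traces <- lapply(1:25, function(i) {
    tr <- rnorm(len, 0, 5)                    # clean background, wide margins
    tr[inside] <- runif(length(inside), -5000, 5000)
    tr
  })
  ep <- detect_artifacts(art_epoch_set(traces))
  expect_equal(count_artifacts(ep), 0)
})

test_that("manual overrides update flags, keep provenance, and log actions", {
  set.seed(12)
  traces <- list(c(rep(0, 60), rep(120, 68)), rnorm(128, 0, 5))
  ep <- detect_artifacts(art_epoch_set(traces))
  expect_true(length(ep$artifact_flags[[1]]) > 0)
  ov <- data.frame(epoch = c(1L, 2L), action = c("unmark", "mark"),
                   reason = c("frontal step is an eye blink", "visual"))
  ep2 <- apply_manual_overrides(ep, ov)
  expect_identical(ep2$artifact_flags[[1]], character(0))
  expect_identical(ep2$artifact_flags[[2]], "manual")
  expect_identical(ep2$auto_flags[[1]], ep$auto_flags[[1]])  # provenance
  expect_equal(nrow(ep2$manual_overrides), 2)
  expect_identical(apply_manual_overrides(ep, ov[0, ]), ep)  # empty = identity
  expect_error(apply_manual_overrides(ep, data.frame(epoch = 99L,
                                                     action = "mark",
                                                     reason = "")), "unknown")
  expect_equal(count_artifacts(ep2), 1)
})

test_that("injected large artifacts are recovered with full sensitivity, clean epochs spared", {
  cfg <- small_cfg(seed = 13, n_stimuli = 40,
                   blink_amplitude_uv = 500, muscle_amplitude_uv = 180)
  sim <- generate_recording(cfg)
  gt <- sim$ground_truth
  rec <- sim$recording
  rec$bad_channels <- gt$flat_channels
  rec <- average_reference(rec)
  ep <- detect_artifacts(baseline_correct(extract_epochs(rec)))
  flagged <- lengths(ep$artifact_flags) > 0
  # what the detector sees from the artifacts alone: blink + muscle
  # contributions on the referenced channels, baselined per epoch
  g <- nrow(gt$mixing)
  R <- diag(g) - matrix(1 / g, g, g)
  art <- (R %*% gt$mixing[, c("blink", "muscle")]) %*%
    gt$sources[c("blink", "muscle"), ]
  rel <- (-205):306
  bl <- rel < 0 & rel >= -205
  masked <- rel / 2048 * 1000 >= -2 & rel / 2048 * 1000 <= 2
  peaks <- vapply(gt$onsets, function(o) {
    seg <- art[, o + rel, drop = FALSE]
    seg <- seg - rowMeans(seg[, bl, drop = FALSE])
    max(abs(seg[, !masked]))
  }, numeric(1))
  big <- peaks > 2 * artifact_rules()$abs_thresh_uv
  clean <- peaks < 20
  expect_gt(sum(big), 0)
  expect_gt(sum(clean), 5)
  expect_true(all(flagged[big]))                       # sensitivity 1.0
  expect_gte(sum(!flagged[clean]) / sum(clean), 0.99)  # specificity
})
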