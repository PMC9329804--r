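test_that("band decomposition separates tones into the right bands", {
  fs <- 256
  t <- seq(1 / fs, 12, by = 1 / fs)
  bp <- band_decompose(sin(2 * pi * 10 * t), fs)
  expect_gt(bp$alpha, 10 * (bp$theta + bp$beta))
  # cross-check against the FIR band-power oracle
  expect_equal(bp$alpha / length(t),
               oracle_band_power(sin(2 * pi * 10 * t), fs, 8, 13),
               tolerance = 0.05)
  two <- band_decompose(sin(2 * pi * 5 * t) + sin(2 * pi * 20 * t), fs)
  expect_equal(two$theta / two$beta, 1, tolerance = 0.2)
  expect_lt(two$alpha, 0.1 * two$theta)
  zero <- band_decompose(numeric(fs), fs)
  expect_true(all(unlist(zero) < 1e-20))
  expect_error(band_decompose(numeric(10), fs), "1 s")
})

test_that("the fused fatigue index is the mean of the two ratios", {
  expect_equal(fatigue_index(1, 1, 1), 1.5)
  expect_equal(fatigue_index(0, 0, 1), 0)
  expect_equal(fatigue_index(2, 3, 4), ((2 + 3) / 4 + 2 / 4) / 2)
  # strictly increasing in theta
  expect_gt(fatigue_index(2, 1, 1), fatigue_index(1, 1, 1))
  # weight exposes the two components
  expect_equal(fatigue_index(1, 1, 2, w = 1), 1)
  expect_equal(fatigue_index(1, 1, 2, w = 0), 0.5)
  expect_error(fatigue_index(1, 1, 0), "beta")
  # scale invariance: common power scaling cancels in the ratios
  expect_equal(fatigue_index(3 * 2, 3 * 5, 3 * 4), fatigue_index(2, 5, 4))
})

test_that("channel selection thresholds the index-vs-time correlation", {
  mk_series <- function(vals) {
    by_channel <- tibble::tibble(channel = "P1",
                                 trial = seq_along(vals),
                                 theta = 1, alpha = 1, beta = 1,
                                 index = vals)
    structure(list(index = tibble::tibble(trial = seq_along(vals),
                                          index = vals),
                   by_channel = by_channel, session_mean = mean(vals),
                   channels = "P1", selected = NULL, threshold = NULL),
              class = "fatigue_series")
  }
  rising <- select_sensitive_channels(mk_series(c(1, 2, 3, 4)))
  expect_equal(rising$selected, "P1")
  expect_equal(rising$correlations$r, 1)
  flat <- select_sensitive_channels(mk_series(rep(2, 4)))
  expect_equal(flat$correlations$r, 0)
  expect_length(flat$selected, 0)
  falling <- select_sensitive_channels(mk_series(c(4, 3, 2, 1)))
  expect_length(falling$selected, 0)   # one-sided: r > threshold only
  expect_error(select_sensitive_channels(mk_series(c(1, 2))), "3 trials")
})

test_that("drift channels are selected with full recall and no false alarms", {
  ep <- demo_epochs()     # drift planted on P2 and P4 only
  ser <- fatigue_timecourse(ep)
  ser <- select_sensitive_channels(ser, threshold = 0.75)
  expect_setequal(ser$selected, c("P2", "P4"))
  expect_true(all(ser$correlations$r[ser$correlations$channel %in%
                                       c("P2", "P4")] > 0.75))
  expect_true(all(ser$correlations$r[!ser$correlations$channel %in%
                                       c("P2", "P4")] < 0.75))
})

test_that("fatigue time course rises with planted drift and is flat without", {
  ep <- demo_epochs()
  ser <- fatigue_timecourse(ep, channels = c("P2", "P4"))
  fit <- stats::lm(index ~ trial, data = ser$index)
  sl <- summary(fit)$coefficients
  expect_gt(sl["trial", "Estimate"], 0)
  expect_lt(sl["trial", "Pr(>|t|)"], 0.01)
  expect_gt(ser$session_mean, 0)
  # no-drift channel: slope indistinguishable from zero (|slope| < 2 SE)
  ser0 <- fatigue_timecourse(ep, channels = "C4")
  sl0 <- summary(stats::lm(index ~ trial, data = ser0$index))$coefficients
  expect_lt(abs(sl0["trial", "Estimate"]), 2 * sl0["trial", "Std. Error"])
  # determinism
  ep2 <- eeg_epoch(generate_session(demo_session_config()))
  ser2 <- fatigue_timecourse(ep2, channels = c("P2", "P4"))
  expect_equal(ser2$index, ser$index)
  expect_error(fatigue_timecourse(ep, channels = character(0)), "empty")
  expect_error(fatigue_timecourse(ep, channels = "XX"), "unknown")
})

test_that("welch PSD satisfies Parseval and resolves band structure", {
  fs <- 256
  set.seed(42)
  x <- rnorm(10 * fs)
  psd <- welch_psd(x, fs)
  df <- psd$freq[2] - psd$freq[1]
  expect_equal(sum(psd$psd) * df, stats::var(x), tolerance = 0.15)
  t <- seq(1 / fs, 10, by = 1 / fs)
  tone <- sin(2 * pi * 10 * t) + 0.1 * rnorm(length(t))
  p <- welch_psd(tone, fs)
  expect_equal(p$freq[which.max(p$psd)], 10, tolerance = 1)
  expect_gt(psd_band_power(p, c(8, 13)), 10 * psd_band_power(p, c(14, 30)))
})
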