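sine_epochs <- function(freq = 10, amp = 1, fs = 256, n_trials = 2) {
  t <- seq(1 / fs, 5, by = 1 / fs)
  arr <- array(rep(amp * sin(2 * pi * freq * t), n_trials),
               dim = c(1, length(t), n_trials),
               dimnames = list("C3", NULL, NULL))
  structure(list(data = arr, fs = fs, labels = "C3",
                 classes = rep("right", n_trials),
                 trial_order = seq_len(n_trials),
                 window = c(0, 5), baseline = c(0, 1)),
            class = "eeg_epochs")
}

test_that("the Morlet map localizes an oscillation and scales quadratically", {
  tfr <- tf_morlet(sine_epochs(freq = 10), "C3", freqs = 4:30)
  peak_row <- which.max(rowMeans(tfr$power))
  expect_equal(tfr$freqs[peak_row], 10, tolerance = 1)
  tfr2 <- tf_morlet(sine_epochs(freq = 10, amp = 2), "C3", freqs = 4:30)
  mid <- which(tfr$times > 1 & tfr$times < 4)
  expect_equal(mean(tfr2$power[peak_row, mid]) /
                 mean(tfr$power[peak_row, mid]), 4, tolerance = 0.01)
  expect_error(tf_morlet(sine_epochs(), "Cz"), "unknown channel")
  expect_error(tf_morlet(sine_epochs(), "C3", freqs = c(10, 200)), "fs/2")
})

test_that("erd_quantify implements baseline-relative power change", {
  tfr <- tf_morlet(sine_epochs(), "C3", freqs = 4:30)
  # stationary oscillation: imagery window equals baseline -> ERD ~ 0
  v0 <- erd_quantify(tfr, band = c(8, 13), window = c(1, 2.5))
  expect_equal(v0$erd, 0, tolerance = 0.05)
  # halved power everywhere vs baseline -> exactly -0.5 on a flat map
  flat <- structure(list(power = matrix(2, nrow = 27, ncol = 1280),
                         freqs = 4:30, times = seq(0, 5, length.out = 1280),
                         baseline = c(0, 1), channel = "C3",
                         normalized = FALSE), class = "eeg_tfr")
  tfr_half <- flat
  bi <- flat$times >= 0 & flat$times < 1
  tfr_half$power[, !bi] <- 0.5 * flat$power[, !bi]
  v <- erd_quantify(tfr_half, band = c(8, 13), window = c(2, 4))
  expect_equal(v$erd, -0.5, tolerance = 1e-12)
  # scale invariance of the ratio definition
  tfr_scaled <- tfr_half
  tfr_scaled$power <- tfr_half$power * 7.3
  expect_equal(erd_quantify(tfr_scaled, c(8, 13), c(2, 4))$erd, v$erd)
  # degenerate baseline
  tfr_zero <- tfr
  tfr_zero$power[, ] <- 0
  expect_error(erd_quantify(tfr_zero, c(8, 13), c(1, 2.5)), "zero baseline")
})

test_that("planted ERD attenuation is recovered from synthetic epochs", {
  ep <- demo_epochs()
  tfr <- tf_morlet(ep, "C3", freqs = 4:30, class = "right")
  v <- erd_quantify(tfr, band = c(8, 13), window = c(1.5, 4.5))
  expect_equal(v$erd, -0.5, tolerance = 0.15)
  # contralateral control: left-hand trials on C3 show no ERD
  tfr_l <- tf_morlet(ep, "C3", freqs = 4:30, class = "left")
  v_l <- erd_quantify(tfr_l, band = c(8, 13), window = c(1.5, 4.5))
  expect_gt(v_l$erd, -0.2)
})

test_that("larger planted attenuation gives a more negative ERD value", {
  vals <- vapply(c(0.3, 0.5, 0.7), function(a) {
    cfg <- demo_session_config()
    cfg$erd_attenuation <- a
    cfg$trials_per_run <- 20L
    ep <- eeg_epoch(generate_session(cfg))
    tfr <- tf_morlet(ep, "C3", freqs = 4:30, class = "right")
    erd_quantify(tfr, c(8, 13), c(1.5, 4.5))$erd
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_equal(vals, -c(0.3, 0.5, 0.7), tolerance = 0.15)
})

test_that("the pooled-variance t-test reproduces its worked examples", {
  # preparation (0-1 s) vs execution (1-2.5 s) alpha-band ERD triples
  c3 <- erd_ttest(c(-0.45044, -0.31794, -0.56522),
                  c(-0.94739, -1.0896, -1.6016))
  expect_equal(c3$p, 0.021975815, tolerance = 1e-6)
  expect_equal(c3$df, 4)
  c4 <- erd_ttest(c(0.026749, -0.047736, 0.20375),
                  c(-0.51328, -0.34357, -0.15104))
  expect_equal(c4$p, 0.036622313, tolerance = 1e-6)
  # identical groups with internal spread: t = 0, p = 1
  same <- erd_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(erd_ttest(c(1, 1), c(1, 1)), "zero pooled variance")
  expect_error(erd_ttest(1, c(1, 2)))
})
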