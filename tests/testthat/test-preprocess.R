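make_rec <- function(x, fs, labels = "C3") {
  mifatigue:::new_eeg_recording(matrix(x, nrow = length(labels),
                                       byrow = TRUE),
                                fs, labels,
                                tibble::tibble(sample = integer(0),
                                               trial = integer(0),
                                               class = character(0)))
}

test_that("band-pass keeps the passband and crushes 50 Hz and DC", {
  # the default 1 Hz transition filter spans ~3.3 s per pass, so use a
  # 30 s tone and measure well inside the interior
  fs <- 512
  t <- seq(0, 30, by = 1 / fs)[-1]
  mid <- seq(10 * fs, 20 * fs)
  tone10 <- make_rec(sin(2 * pi * 10 * t), fs)
  out10 <- eeg_bandpass(tone10)$data[1, ]
  gain <- sqrt(mean(out10[mid]^2) / mean(sin(2 * pi * 10 * t[mid])^2))
  expect_gt(gain, 10^(-1 / 20))       # within 1 dB
  expect_lt(gain, 10^(1 / 20))

  tone50 <- make_rec(sin(2 * pi * 50 * t), fs)
  out50 <- eeg_bandpass(tone50)$data[1, mid]
  expect_lt(sqrt(mean(out50^2)), 0.01)

  dc <- make_rec(rep(5, length(t)), fs)
  outdc <- eeg_bandpass(dc)$data[1, mid]
  expect_lt(max(abs(outdc)), 0.05)
})

test_that("band-pass rejects an upper edge at or above Nyquist", {
  rec <- make_rec(rnorm(512), 64)
  expect_error(eeg_bandpass(rec, 1, 32), "Nyquist")
})

test_that("filtering commutes with epoching away from edges", {
  rec <- demo_recording()
  filt <- eeg_bandpass(rec, taps = 257)
  ep_then <- eeg_epoch(filt)
  # filter one epoch-sized segment with generous margins, then crop
  o <- rec$events$sample[3]
  fs <- rec$fs
  marg <- 2 * fs
  seg <- rec
  seg$data <- rec$data[, (o - marg):(o + 5 * fs - 1 + marg), drop = FALSE]
  seg$events <- tibble::tibble(sample = marg + 1L, trial = 3L,
                               class = rec$events$class[3])
  ep_seg <- eeg_epoch(eeg_bandpass(seg, taps = 257))
  expect_equal(ep_seg$data[, , 1], ep_then$data[, , 3], tolerance = 1e-6)
})

test_that("resampling preserves sinusoids and rescales events", {
  fs <- 1024
  t <- seq(1 / fs, 4, by = 1 / fs)
  rec <- make_rec(sin(2 * pi * 10 * t), fs)
  rec$events <- tibble::tibble(sample = 1025L, trial = 1L, class = "left")
  same <- eeg_resample(rec, fs)
  expect_identical(same$data, rec$data)
  down <- eeg_resample(rec, 512)
  expect_equal(down$fs, 512)
  expect_equal(down$events$sample, 513L)
  # decimated grid keeps every other original instant: t2[k] = t[2k-1]
  t2 <- t[seq(1, length(t), by = 2)]
  mid <- seq(256, length(t2) - 256)
  expect_gt(cor(down$data[1, mid], sin(2 * pi * 10 * t2[mid])), 0.999)
  expect_error(eeg_resample(rec, 2048), "exceed")
})

test_that("epoching cuts one baseline-corrected epoch per event", {
  rec <- tiny_recording()
  ep <- eeg_epoch(rec)
  expect_equal(dim(ep$data)[3], 4)
  expect_equal(dim(ep$data)[2], 5 * rec$fs)
  expect_equal(ep$classes, rec$events$class)
  # baseline window mean is zero per channel and trial
  b <- apply(ep$data[, seq_len(rec$fs), , drop = FALSE], c(1, 3), mean)
  expect_lt(max(abs(b)), 1e-9)
  # baseline removal is idempotent
  again <- mifatigue:::remove_baseline(ep)
  expect_equal(again$data, ep$data)
  # constant channel becomes identically zero
  rec2 <- rec
  rec2$data[1, ] <- 3.3
  ep2 <- eeg_epoch(rec2)
  expect_true(all(abs(ep2$data[1, , ]) < 1e-12))
})

test_that("epochs outside the recording raise an error listing events", {
  rec <- tiny_recording()
  rec$events$sample[2] <- ncol(rec$data) - 10L
  expect_error(eeg_epoch(rec), "2")
})

test_that("the artifact hook is a validated pass-through", {
  ep <- demo_epochs()
  expect_identical(reject_artifacts(ep), ep)
  expect_error(reject_artifacts(ep, hook = function(e) "nope"))
})
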