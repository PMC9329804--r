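test_that("generation is deterministic by seed and differs across seeds", {
  cfg <- session_config(n_runs = 1, trials_per_run = 4, fs = 128,
                        channels = c("C3", "C4", "P6", "F3"),
                        blank_s = 0.5, cue_s = 0.5, seed = 7,
                        coupled_pairs = data.frame(parietal = "P6",
                                                   frontal = "F3",
                                                   strength = 0.5))
  a <- generate_session(cfg)
  b <- generate_session(cfg)
  expect_identical(a$data, b$data)
  expect_identical(a$events, b$events)
  cfg2 <- cfg
  cfg2$seed <- 8L
  expect_false(identical(generate_session(cfg2)$data, a$data))
})

test_that("event schedule matches the configured trial counts and balance", {
  rec <- tiny_recording()
  expect_equal(nrow(rec$events), 4)
  expect_equal(sort(unique(rec$events$class)), c("left", "right"))
  expect_equal(sum(rec$events$class == "left"), 2)
  rec40 <- demo_recording()
  expect_equal(nrow(rec40$events), 40)
  expect_equal(sum(rec40$events$class == "left"), 20)
  expect_true(all(rec40$events$sample >= 1 &
                    rec40$events$sample <= ncol(rec40$data)))
  expect_equal(rec40$events$trial, seq_len(40))
})

test_that("planted ERD attenuation is recoverable by a band-power oracle", {
  # low-noise session; alpha power on C3 during right-hand imagery
  # (1-5 s after onset) over the 0-1 s baseline should be ~ 1 - 0.5
  rec <- demo_recording()
  fs <- rec$fs
  x <- band_filter_fft(rec$data["C3", ], fs, 8, 13)
  on <- rec$events$sample[rec$events$class == "right"]
  base <- unlist(lapply(on, function(o) x[o:(o + fs - 1)]))
  imag <- unlist(lapply(on, function(o) x[(o + fs):(o + 5 * fs - 1)]))
  expect_equal(mean(imag^2) / mean(base^2), 0.5, tolerance = 0.2)
  # ipsilateral channel (left trials) keeps full power
  onl <- rec$events$sample[rec$events$class == "left"]
  basel <- unlist(lapply(onl, function(o) x[o:(o + fs - 1)]))
  imagl <- unlist(lapply(onl, function(o) x[(o + fs):(o + 5 * fs - 1)]))
  expect_equal(mean(imagl^2) / mean(basel^2), 1, tolerance = 0.2)
})

test_that("planted fatigue drift and coupling strength shape the signal", {
  rec <- demo_recording()
  fs <- rec$fs
  # theta power on the drift channel P2 roughly triples across the session
  th <- band_filter_fft(rec$data["P2", ], fs, 4, 7)
  trial_pow <- vapply(rec$events$sample, function(o)
    mean(th[o:(o + 5 * fs - 1)]^2), numeric(1))
  first_q <- mean(trial_pow[1:10])
  last_q <- mean(trial_pow[31:40])
  expect_gt(last_q / first_q, 1.8)
  # non-drift channel C4 stays flat
  th2 <- band_filter_fft(rec$data["C4", ], fs, 4, 7)
  tp2 <- vapply(rec$events$sample, function(o)
    mean(th2[o:(o + 5 * fs - 1)]^2), numeric(1))
  expect_lt(mean(tp2[31:40]) / mean(tp2[1:10]), 1.5)
  # coupled pair shares an alpha component: correlation of alpha-band
  # signals grows with strength
  cors <- vapply(c(0, 0.5, 1), function(s) {
    cfg <- session_config(n_runs = 1, trials_per_run = 4, fs = 128,
                          channels = c("P6", "F3"), blank_s = 0.5,
                          cue_s = 0.5, noise_sd = 0.1,
                          erd_channels = c(right = "P6", left = "F3"),
                          erd_attenuation = 0,
                          coupled_pairs = data.frame(parietal = "P6",
                                                     frontal = "F3",
                                                     strength = s),
                          seed = 5)
    r <- generate_session(cfg)
    abs(cor(band_filter_fft(r$data["P6", ], 128, 8, 13),
            band_filter_fft(r$data["F3", ], 128, 8, 13)))
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
  expect_gt(cors[3], 0.95)
})

test_that("invalid configurations are rejected", {
  expect_error(session_config(erd_attenuation = 1), "erd_attenuation")
  expect_error(session_config(erd_attenuation = -0.1), "erd_attenuation")
  expect_error(session_config(channels = c("C3", "C3", "C4")), "unique")
  expect_error(session_config(channels = c("C3", "Cz"),
                              erd_channels = c(right = "C3", left = "C4")),
               "C4")
  expect_error(
    session_config(channels = c("C3", "C4", "P6"),
                   coupled_pairs = data.frame(parietal = "P6",
                                              frontal = "F9",
                                              strength = 0.5)),
    "F9")
  expect_error(
    session_config(channels = c("C3", "C4", "P6", "F3"),
                   coupled_pairs = data.frame(parietal = "P6",
                                              frontal = "F3",
                                              strength = 1.2)),
    "strength")
})

test_that("age-group presets encode opposite spectral trends", {
  young <- session_preset("young")
  old <- session_preset("elderly")
  expect_gt(young$coupled_pairs$strength[1], old$coupled_pairs$strength[1])
  expect_equal(unique(young$coupled_pairs$parietal), "P6")
  expect_equal(unique(old$coupled_pairs$parietal), "P2")
  # young concentrate power into theta; elderly flatten towards even shares
  share_entropy <- function(cfg, frac) {
    p <- cfg$band_amp^2 * (1 + cfg$fatigue_drift * frac)
    rhythm_entropy(p / sum(p))
  }
  expect_lt(share_entropy(young, 1), share_entropy(young, 0))
  expect_gt(share_entropy(old, 1), share_entropy(old, 0))
})
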