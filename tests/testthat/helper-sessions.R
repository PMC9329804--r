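# Shared synthetic sessions, generated once per test run and cached.
# Small montages and compressed inter-trial gaps keep the suite fast; the
# statistical structure (ERD, drift, coupling) matches the full paradigm.

.session_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .session_cache))
    assign(key, force(expr), envir = .session_cache)
  get(key, envir = .session_cache)
}

test_channels <- function() {
  c("C3", "C4", "P1", "P2", "P4", "P6", "F3", "F4", "F5", "F1", "F2", "F6")
}

# 40-trial single-run session at 256 Hz with ERD 0.5, strong (high-SNR)
# theta-dominant drift on P2/P4, and alpha coupling P6 <-> frontal at 0.6.
demo_session_config <- function(seed = 3) {
  session_config(
    n_runs = 1, trials_per_run = 40, fs = 256, channels = test_channels(),
    blank_s = 0.5, cue_s = 0.5,
    erd_attenuation = 0.5, noise_sd = 0.3,
    fatigue_drift = c(theta = 3.5, alpha = 1.5, beta = -0.3),
    drift_channels = c("P2", "P4"),
    coupled_pairs = data.frame(parietal = "P6", frontal = mi_frontal_set(),
                               strength = 0.6),
    seed = seed)
}

demo_recording <- function() cached("demo_rec", generate_session(demo_session_config()))

demo_epochs <- function() cached("demo_epochs", eeg_epoch(demo_recording()))

# tiny 4-trial session for plumbing tests
tiny_recording <- function() {
  cached("tiny_rec", generate_session(session_config(
    n_runs = 1, trials_per_run = 4, fs = 128,
    channels = c("C3", "C4", "P6", "F3"),
    blank_s = 0.5, cue_s = 0.5, noise_sd = 0.5,
    coupled_pairs = data.frame(parietal = "P6", frontal = "F3",
                               strength = 0.5),
    seed = 9)))
}

# direct band-power oracle: sharp FIR band-pass (time-domain convolution)
# + mean square, the independent route against the package's spectral-mask
# reconstruction; needs signals several times the ~1 s transition width
oracle_band_power <- function(x, fs, lo, hi) {
  b <- signal::fir1(round(1.65 * fs) * 2, c(lo, hi) / (fs / 2), type = "pass")
  y <- stats::filter(x, b, sides = 2)
  y <- y[!is.na(y)]
  mean(y^2)
}
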