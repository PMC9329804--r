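#' Zero-phase FIR band-pass filter for a recording
#'
#' Designs a windowed-sinc (Hamming) FIR band-pass with [signal::fir1()] and
#' applies it forward-backward (squared magnitude response, zero phase) via
#' FFT convolution, so ERD latencies are not shifted. The default 1-35 Hz
#' band also removes 50 Hz mains interference: with the default filter
#' length the single-pass attenuation at 50 Hz exceeds 50 dB, i.e. > 100 dB
#' after the two passes. Edge transients (one filter length at each end) are
#' attenuated toward zero; epochs should not start within them.
#'
#' @param rec an `eeg_recording`.
#' @param lo,hi passband edges (Hz).
#' @param taps FIR length (odd); default gives a ~1 Hz transition band
#'   (`3.3 * fs / 1` rounded up to odd), sharp enough that DC lies in the
#'   stopband even with `lo = 1`.
#' @return Filtered `eeg_recording`.
#' @export
eeg_bandpass <- function(rec, lo = 1, hi = 35, taps = NULL) {
  stopifnot(inherits(rec, "eeg_recording"), lo < hi)
  if (hi >= rec$fs / 2)
    stop("upper edge (", hi, " Hz) must be below the Nyquist frequency (",
         rec$fs / 2, " Hz)")
  if (is.null(taps)) taps <- round(3.3 * rec$fs) %/% 2 * 2 + 1
  b <- signal::fir1(taps - 1, c(lo, hi) / (rec$fs / 2), type = "pass")
  out <- rec
  out$data <- t(apply(rec$data, 1, fir_filtfilt_fft, b = b))
  dimnames(out$data) <- dimnames(rec$data)
  out
}

# Forward-backward FIR by FFT: multiplying the spectrum by |B|^2 convolves
# with the (symmetric, centered) autocorrelation of b — zero phase with no
# crop offset. The zero padding (>= one kernel length each side) turns the
# circular convolution into a linear one, so interior samples are identical
# whether the filter is applied to the whole recording or to any segment
# containing their kernel support.
fir_filtfilt_fft <- function(x, b) {
  n <- length(x)
  L <- length(b)
  nfft <- stats::nextn(n + 2L * L, 2)
  B <- stats::fft(c(b, numeric(nfft - L)))
  X <- stats::fft(c(x, numeric(nfft - n)))
  y <- Re(stats::fft(X * B * Conj(B), inverse = TRUE)) / nfft
  y[seq_len(n)]
}

#' Resample a recording
#'
#' Anti-aliased downsampling of every channel. Integer rate ratios (the
#' usual 1024 -> 512 Hz) use a zero-phase windowed-sinc low-pass (cutoff
#' 0.95 of the new Nyquist) followed by decimation — a polyphase filter in
#' its simplest exact form; other ratios use Fourier-domain resampling.
#' Event sample indices are rescaled and rounded.
#'
#' @param rec an `eeg_recording`.
#' @param fs_new target rate (Hz), at most `rec$fs`.
#' @return Resampled `eeg_recording`.
#' @export
eeg_resample <- function(rec, fs_new = 512) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (fs_new > rec$fs) stop("fs_new must not exceed the original rate")
  if (fs_new == rec$fs) return(rec)
  q <- rec$fs / fs_new
  out <- rec
  if (abs(q - round(q)) < 1e-9) {
    q <- round(q)
    b <- signal::fir1(200, 0.95 / q)
    res <- apply(rec$data, 1, function(x)
      fir_filtfilt_fft(x, b)[seq(1, length(x), by = q)])
  } else {
    res <- apply(rec$data, 1, resample_fourier, fs = rec$fs, fs_new = fs_new)
  }
  out$data <- t(res)
  dimnames(out$data) <- dimnames(rec$data)
  out$fs <- fs_new
  out$events$sample <- as.integer(round((rec$events$sample - 1) *
                                          fs_new / rec$fs)) + 1L
  out$events <- out$events[out$events$sample <= ncol(out$data), ]
  out
}

# Brick-wall band-limited resampling via the DFT: keep the frequency bins
# below the new Nyquist and invert at the new length.
resample_fourier <- function(x, fs, fs_new) {
  n <- length(x)
  m <- floor(n * fs_new / fs)
  X <- stats::fft(x)
  Y <- complex(m)
  half <- (m - 1) %/% 2
  Y[1] <- X[1]
  Y[1 + seq_len(half)] <- X[1 + seq_len(half)]
  Y[m + 1 - seq_len(half)] <- X[n + 1 - seq_len(half)]
  if (m %% 2 == 0) Y[m / 2 + 1] <- Re(X[m / 2 + 1])
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Cut trial epochs and remove the baseline
#'
#' One epoch per event, spanning `window` seconds relative to imagery onset.
#' The per-channel mean over `baseline` (default the 0-1 s preparation
#' period) is subtracted from the whole epoch. Baseline removal is
#' idempotent.
#'
#' @param rec an `eeg_recording`.
#' @param window `c(t0, t1)` epoch span in seconds relative to each event.
#' @param baseline `c(b0, b1)` baseline span in seconds (inside `window`).
#' @return An `eeg_epochs`: `data` is a channels x samples x trials array;
#'   `classes`, `trial_order`, `fs`, `labels`, `window`, `baseline` attached.
#' @export
eeg_epoch <- function(rec, window = c(0, 5), baseline = c(0, 1)) {
  stopifnot(inherits(rec, "eeg_recording"), window[2] > window[1],
            baseline[1] >= window[1], baseline[2] <= window[2])
  fs <- rec$fs
  n <- ncol(rec$data)
  i0 <- rec$events$sample + round(window[1] * fs)
  i1 <- rec$events$sample + round(window[2] * fs) - 1L
  bad <- which(i0 < 1 | i1 > n)
  if (length(bad))
    stop("epoch window exceeds recording bounds for event(s): ",
         paste(rec$events$trial[bad], collapse = ", "))
  len <- i1[1] - i0[1] + 1L
  arr <- array(0, dim = c(nrow(rec$data), len, length(i0)),
               dimnames = list(rec$labels, NULL, NULL))
  for (t in seq_along(i0)) arr[, , t] <- rec$data[, i0[t]:i1[t]]
  ep <- structure(list(data = arr, fs = fs, labels = rec$labels,
                       classes = rec$events$class,
                       trial_order = seq_along(i0),
                       window = window, baseline = baseline),
                  class = "eeg_epochs")
  remove_baseline(ep)
}

remove_baseline <- function(epochs) {
  b0 <- round((epochs$baseline[1] - epochs$window[1]) * epochs$fs) + 1L
  b1 <- round((epochs$baseline[2] - epochs$window[1]) * epochs$fs)
  base <- apply(epochs$data[, b0:b1, , drop = FALSE], c(1, 3), mean)
  for (t in seq_len(dim(epochs$data)[3]))
    epochs$data[, , t] <- epochs$data[, , t] - base[, t]
  epochs
}

#' Artifact-rejection hook
#'
#' Pass-through placeholder for component-based artifact rejection (e.g. ICA
#' with automatic component labelling, retaining components classified as
#' brain EEG with >= 60% probability). Synthetic sessions are artifact-free,
#' so the default hook returns its input; users running real data can supply
#' their own function of an `eeg_epochs`.
#'
#' @param epochs an `eeg_epochs`.
#' @param hook a function `eeg_epochs -> eeg_epochs`, default identity.
#' @return An `eeg_epochs`.
#' @export
reject_artifacts <- function(epochs, hook = identity) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  out <- hook(epochs)
  stopifnot(inherits(out, "eeg_epochs"))
  out
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz; window [%g, %g] s, baseline [%g, %g] s\n",
              d[3], d[1], d[2], x$fs, x$window[1], x$window[2],
              x$baseline[1], x$baseline[2]))
  invisible(x)
}
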